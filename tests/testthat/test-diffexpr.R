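test_that("a planted batch factor orthogonal to the groups is recovered as SV1", {
  set.seed(2)
  n <- 60; g <- 500
  design <- stats::model.matrix(~ 0 + rep(c("Female_A", "Male_A"), each = n / 2))
  batch <- rnorm(n)
  e <- matrix(rnorm(g * n, sd = 0.5), g, n) + outer(rnorm(g), batch) * 0.8
  sv <- estimate_surrogate_covariates(e, design, n_max = 5, seed = 1)
  expect_gte(ncol(sv), 1)
  expect_gt(abs(cor(sv[, 1], batch)), 0.9)
})

test_that("parallel analysis retains no components from pure noise in most seeds", {
  ks <- vapply(1:10, function(s) {
    set.seed(s)
    e <- matrix(rnorm(300 * 40), 300, 40)
    ncol(estimate_surrogate_covariates(e, stats::model.matrix(~ rep(0:1, 20)),
                                       n_max = 5, seed = s))
  }, 0L)
  expect_gte(mean(ks == 0L), 0.9)
})

test_that("surrogate estimation respects n_max = 0 and fixed n_sv, and covariates pass through", {
  set.seed(3)
  e <- matrix(rnorm(100 * 20), 100, 20)
  design <- stats::model.matrix(~ rep(0:1, 10))
  expect_equal(ncol(estimate_surrogate_covariates(e, design, n_max = 0)), 0)
  expect_equal(ncol(estimate_surrogate_covariates(e, design, n_max = 5,
                                                  n_sv = 3)), 3)
  sam <- data.frame(sample_id = paste0("s", 1:20),
                    sex = rep(c("Female", "Male"), 10),
                    region = "A", donor = paste0("d", 1:20))
  covs <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("RIN", "PMI")))
  d <- make_design(sam, covariates = covs)
  expect_true(all(c("RIN", "PMI") %in% colnames(d$design)))
  expect_equal(d$design[, "RIN"], covs[, "RIN"], ignore_attr = TRUE)
})

test_that("voom weights are positive, near-flat trends give near-equal weights, and noisy samples are downweighted", {
  set.seed(4)
  n <- 200
  design <- stats::model.matrix(~ rep(0:1, n / 2))
  ## flat mean-variance structure: all genes at the same abundance
  cnt <- matrix(rnbinom(300 * n, mu = 200, size = 20), 300, n)
  v <- voom_transform(cnt, NULL, design)
  expect_true(all(is.finite(v$weights)) && all(v$weights > 0))
  expect_lt(max(v$obs_weights) / min(v$obs_weights), 2)

  ## a sample with inflated noise gets the minimum quality weight
  d2 <- small_bulk(seed = 5, n_genes = 400, n_donors = 20,
                   regions = "Cortex")
  cnt2 <- d2$counts
  set.seed(6)
  noisy <- 3
  cnt2[, noisy] <- as.integer(pmax(0, round(
    cnt2[, noisy] * exp(rnorm(nrow(cnt2), 0, 1.2)))))
  v2 <- voom_transform(cnt2, tmm_factors(cnt2),
                       make_design(d2$samples)$design)
  expect_equal(unname(which.min(v2$sample_weights)), noisy)
  expect_true(all(v2$sample_weights >= 0.1 & v2$sample_weights <= 10))
})

test_that("consensus donor correlation tracks within-donor dependence", {
  set.seed(7)
  n_donor <- 25; g <- 600
  donors <- rep(paste0("d", 1:n_donor), each = 2)
  design <- stats::model.matrix(~ rep(0:1, n_donor))
  ## duplicated donor samples plus tiny jitter: near-perfect correlation
  base <- matrix(rnorm(g * n_donor), g, n_donor)
  dup <- base[, rep(1:n_donor, each = 2)] + matrix(rnorm(g * 2 * n_donor, sd = 0.05), g)
  rho_hi <- estimate_duplicate_correlation(dup, design, donors)
  expect_gt(rho_hi, 0.95)
  expect_lt(abs(rho_hi), 1)

  ## fully independent samples: consensus near zero
  indep <- matrix(rnorm(2000 * 2 * n_donor), 2000)
  rho_0 <- estimate_duplicate_correlation(indep, design, donors)
  expect_lt(abs(rho_0), 0.05)

  expect_error(
    estimate_duplicate_correlation(indep, design, paste0("d", 1:(2 * n_donor))),
    "correlation = 0")
})

test_that("contrast matrices implement female-minus-male and equal-weight omnibus", {
  lv2 <- c("Female_A", "Female_B", "Male_A", "Male_B")
  cm <- make_sex_region_contrasts(lv2)
  expect_equal(cm["Female_A", "A"], 1)
  expect_equal(cm["Male_A", "A"], -1)
  expect_equal(cm["Female_B", "A"], 0)
  expect_equal(unname(cm[, "Omnibus"]),
               unname(rowMeans(cm[, c("A", "B")])))

  regions <- paste0("R", sprintf("%02d", 1:11))
  lv11 <- c(paste0("Female_", regions), paste0("Male_", regions))
  cm11 <- make_sex_region_contrasts(lv11)
  om <- cm11[, "Omnibus"]
  expect_equal(sort(unique(om)), c(-1 / 11, 1 / 11))
  expect_equal(om[paste0("Female_", regions)], rep(1 / 11, 11),
               ignore_attr = TRUE)

  ## single region: omnibus equals the region contrast
  cm1 <- make_sex_region_contrasts(c("Female_A", "Male_A"))
  expect_equal(cm1[, "Omnibus"], cm1[, "A"])
})

test_that("with no blocking, weights or covariates the fit returns exact group means", {
  set.seed(8)
  sam <- data.frame(sample_id = paste0("s", 1:12),
                    sex = rep(c("Female", "Male"), each = 6),
                    region = rep(c("A", "B"), 6),
                    donor = paste0("d", 1:12), stringsAsFactors = FALSE)
  e <- matrix(rnorm(20 * 12, 5), 20, 12,
              dimnames = list(paste0("g", 1:20), sam$sample_id))
  d <- make_design(sam)
  cm <- make_sex_region_contrasts(d$group_levels)
  fit <- fit_gene_models(e, d$design, cm)
  grp_means <- t(apply(e, 1, function(x) tapply(x, d$group, mean)))
  manual <- grp_means[, rownames(cm)] %*% cm
  expect_equal(unclass(fit$coefficients), manual, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("swapping every sex label negates all contrast estimates exactly", {
  d <- small_bulk(seed = 9, n_genes = 300, n_donors = 10)
  sam_sw <- d$samples
  sam_sw$sex <- ifelse(sam_sw$sex == "Female", "Male", "Female")
  e <- log_cpm(d$counts)
  d1 <- make_design(d$samples); d2 <- make_design(sam_sw)
  f1 <- fit_gene_models(e, d1$design, make_sex_region_contrasts(d1$group_levels))
  f2 <- fit_gene_models(e, d2$design, make_sex_region_contrasts(d2$group_levels))
  expect_equal(unclass(f1$coefficients), -unclass(f2$coefficients),
               tolerance = 1e-12)
})

test_that("the omnibus estimate is the arithmetic mean of region estimates", {
  d <- small_bulk(seed = 10, n_genes = 300, n_donors = 10)
  e <- log_cpm(d$counts)
  dd <- make_design(d$samples)
  cm <- make_sex_region_contrasts(dd$group_levels)
  fit <- fit_gene_models(e, dd$design, cm)
  regions <- setdiff(colnames(cm), "Omnibus")
  expect_equal(fit$coefficients[, "Omnibus"],
               rowMeans(fit$coefficients[, regions]), tolerance = 1e-12)
})

## Closed-form moment estimator for the scaled-F prior on residual
## variances (log-variance moment matching), written independently.
moment_prior_oracle <- function(s2, d) {
  trigamma_inverse <- function(x) {
    y <- 0.5 + 1 / x
    for (i in 1:100) {
      tri <- trigamma(y)
      y <- y + tri * (1 - tri / x) / psigamma(y, 2)
    }
    y
  }
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (evar <= 0) return(list(d0 = Inf, s02 = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  list(d0 = d0, s02 = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
}

test_that("empirical-Bayes moderation matches the closed-form moment estimator", {
  s2 <- c(0.5, 1.2, 0.8, 2.0, 0.3)
  d <- 7
  fit <- new("MArrayLM", list(
    coefficients = matrix(1, 5, 1), stdev.unscaled = matrix(1, 5, 1),
    sigma = sqrt(s2), df.residual = rep(d, 5), Amean = rep(5, 5)))
  eb <- limma::eBayes(fit)
  oracle <- moment_prior_oracle(s2, d)
  expect_equal(eb$df.prior, oracle$d0, tolerance = 1e-10)
  expect_equal(eb$s2.prior, oracle$s02, tolerance = 1e-10)
  expect_equal(eb$s2.post,
               (oracle$d0 * oracle$s02 + d * s2) / (oracle$d0 + d),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("identical residual variances produce no shrinkage and t proportional to ordinary t", {
  set.seed(11)
  s2 <- rep(0.7, 30)
  fit <- new("MArrayLM", list(
    coefficients = matrix(rnorm(30), 30, 1),
    stdev.unscaled = matrix(0.2, 30, 1),
    sigma = sqrt(s2), df.residual = rep(10, 30), Amean = rep(5, 30)))
  eb <- limma::eBayes(fit)
  expect_equal(unname(eb$s2.post), s2, tolerance = 1e-9)
  ordinary_t <- fit$coefficients[, 1] / (0.2 * sqrt(s2))
  expect_equal(unname(eb$t[, 1]), unname(ordinary_t), tolerance = 1e-9)
})

test_that("moderate_and_test produces a well-formed annotated DE table", {
  d <- small_bulk(seed = 12, n_genes = 300, n_donors = 12)
  res <- run_de_analysis(d$counts, d$samples, d$genes, n_sv = 0)
  de <- res$de
  expect_s3_class(de, "de_table")
  expect_setequal(unique(de$contrast), c("Cortex", "Cerebellum", "Omnibus"))
  expect_true(all(de$adj.P.Val >= de$P.Value - 1e-15))
  expect_true(all(de$adj.P.Val <= 1 & de$adj.P.Val >= 0))
  expect_false(any(is.na(de$chromosome)))
  ## female-up simulated genes carry positive estimated logFC on average
  up <- rownames(d$truth$lfc)[d$truth$lfc[, "Cortex"] > 0.3 &
                                is.finite(d$truth$lfc[, "Cortex"])]
  ct <- de[de$contrast == "Cortex", ]
  expect_gt(mean(ct$logFC[ct$gene_id %in% up]), 0)
})
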