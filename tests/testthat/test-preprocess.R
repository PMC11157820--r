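test_that("donor-level exclusion removes positive and unknown donors entirely", {
  sam <- data.frame(
    sample_id = paste0("s", 1:6),
    donor = c("d1", "d1", "d2", "d2", "d3", "d3"),
    dementia = c("negative", "negative", "positive", "positive",
                 "negative", "negative"),
    sepsis = c("negative", "negative", "negative", "negative",
               "unknown", "unknown"),
    stringsAsFactors = FALSE)

  ## positive on one field drops that donor; unknown likewise
  out <- exclude_samples(sam, c("dementia", "sepsis"))
  expect_equal(out$donor, c("d1", "d1"))

  ## a single flagged sample removes every sample of that donor
  sam2 <- sam
  sam2$sepsis <- c("unknown", rep("negative", 5))
  out2 <- exclude_samples(sam2, "sepsis")
  expect_false("d1" %in% out2$donor)
  expect_equal(sort(unique(out2$donor)), c("d2", "d3"))

  ## no flags: identity
  sam3 <- sam
  sam3$dementia <- sam3$sepsis <- "negative"
  expect_equal(exclude_samples(sam3, c("dementia", "sepsis"))$sample_id,
               sam3$sample_id)

  ## removal accounting and failure modes
  expect_equal(sum(attr(out, "removed_per_field")), 4L)
  sam4 <- sam
  sam4$dementia <- "positive"
  expect_error(exclude_samples(sam4, "dementia"), "all samples excluded")
  expect_error(exclude_samples(sam, "rin"), "rin")
  sam5 <- sam
  sam5$dementia[1] <- "maybe"
  expect_error(exclude_samples(sam5, "dementia"), "dementia")
})

test_that("the 70%-of-smallest-group rule and CPM cutoff drive gene retention", {
  ## smallest group 27 at 70% -> 19 samples required
  cnt <- matrix(100L, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  mask <- filter_low_expression(cnt, c(27, 50, 101), cpm_cutoff = 10)
  expect_equal(attr(mask, "min_samples"), 19L)

  ## an all-zero gene is always excluded
  cnt2 <- rbind(expressed = c(500L, 500L), silent = c(0L, 0L))
  colnames(cnt2) <- c("s1", "s2")
  m2 <- filter_low_expression(cnt2, c(2), cpm_cutoff = 0.001)
  expect_false(m2["silent"])

  ## library 1e6 each, gene counts (11, 0): CPM = (11, 0), cutoff 10
  cnt3 <- rbind(g1 = c(11L, 0L), filler = c(1e6L - 11L, 1e6L))
  m_strict2 <- filter_low_expression(cnt3, c(2, 2), cpm_cutoff = 10)   # needs 2
  expect_false(m_strict2["g1"])
  m_strict1 <- filter_low_expression(cnt3, c(1, 2), cpm_cutoff = 10)   # needs 1
  expect_true(m_strict1["g1"])

  expect_error(filter_low_expression(cnt, c(27), cpm_cutoff = -1),
               "cpm_cutoff")
})

test_that("filtering is monotone in both the cutoff and the sample threshold", {
  set.seed(1)
  cnt <- matrix(rnbinom(200 * 30, mu = 20, size = 1), 200, 30)
  for (cut in c(1, 5, 10, 50)) {
    lo <- filter_low_expression(cnt, c(10), cpm_cutoff = cut)
    hi <- filter_low_expression(cnt, c(10), cpm_cutoff = cut * 2)
    expect_true(all(lo[hi]))  # every gene kept at the higher cutoff survives the lower
  }
  strict <- filter_low_expression(cnt, c(20), cpm_cutoff = 10)  # 14 samples
  lax <- filter_low_expression(cnt, c(6), cpm_cutoff = 10)      # 5 samples
  expect_true(all(lax[strict]))
})

## Literal evaluation of the doubly trimmed, delta-method-weighted
## mean-of-M-values definition, written independently of edgeR.
tmm_brute_force <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    obs <- counts[, k] / lib[k]
    rf <- counts[, ref] / lib[ref]
    pos <- obs > 0 & rf > 0
    M <- log2(obs / rf)[pos]
    A <- (log2(obs) + log2(rf))[pos] / 2
    v <- ((lib[k] - counts[, k]) / (lib[k] * counts[, k]) +
            (lib[ref] - counts[, ref]) / (lib[ref] * counts[, ref]))[pos]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0)
  f / exp(mean(log(f)))
}

test_that("TMM factors match the trimmed-weighted-mean definition and its fixed points", {
  ## identical columns and pure depth changes leave factors at 1
  cnt <- matrix(rep(c(10L, 200L, 30L, 1000L, 5L), 3), 5, 3)
  expect_equal(tmm_factors(cnt)$norm_factors, rep(1, 3), tolerance = 1e-12)
  cnt2 <- cbind(a = c(10L, 200L, 30L, 1000L, 5L),
                b = 2L * c(10L, 200L, 30L, 1000L, 5L))
  expect_equal(unname(tmm_factors(cnt2)$norm_factors), c(1, 1),
               tolerance = 1e-12)

  ## 3-sample toy with an extreme composition gene: brute-force oracle
  set.seed(7)
  cnt3 <- matrix(rnbinom(300 * 3, mu = 100, size = 3), 300, 3)
  cnt3[1, 3] <- 50000L
  res <- tmm_factors(cnt3)
  expect_equal(res$norm_factors, tmm_brute_force(cnt3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(res$effective_lib_size, colSums(cnt3) * res$norm_factors)
  expect_equal(exp(mean(log(res$norm_factors))), 1, tolerance = 1e-9)
})

test_that("TMM factors are stable under per-sample depth rescaling", {
  ## the delta-method weights are not exactly scale-free, so stability
  ## is approximate, not exact
  set.seed(8)
  cnt <- matrix(rnbinom(400 * 4, mu = 80, size = 2), 400, 4)
  f0 <- tmm_factors(cnt)$norm_factors
  cnt2 <- cnt
  cnt2[, 2] <- cnt2[, 2] * 7L
  f1 <- tmm_factors(cnt2)$norm_factors
  expect_lt(max(abs(f0 - f1)), 0.05)
})

test_that("log_cpm follows its formula and is monotone and scale-stable", {
  ## count 0, library 1e6 - 1, prior 0.5 -> log2(0.5) = -1
  m <- matrix(c(0, 100), 2, 1)
  out <- log_cpm(m, effective_lib_size = 1e6 - 1, prior_count = 0.5)
  expect_equal(out[1, 1], -1)
  expect_equal(out[2, 1], log2(100.5), tolerance = 1e-12)

  ## doubling (count + prior) and (library + 1) leaves the value unchanged
  a <- log_cpm(matrix(7), effective_lib_size = 999, prior_count = 0.5)
  b <- log_cpm(matrix(14.5), effective_lib_size = 1999, prior_count = 0.5)
  expect_equal(a[1, 1], b[1, 1], tolerance = 1e-12)

  ## strictly increasing in count
  v <- log_cpm(matrix(0:50, ncol = 1), effective_lib_size = 1e5)
  expect_true(all(diff(v[, 1]) > 0))
  expect_error(log_cpm(m, 1e6, prior_count = -1), "prior_count")
  expect_error(log_cpm(m, -5), "positive")
})
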