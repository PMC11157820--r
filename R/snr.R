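## Transcriptome-wide signal-to-noise ratio with subsampled true/null
## distributions.
##
## The statistic compares the total male-female difference to the total
## variance of the unadjusted expression matrix:
##
##   tSNR(X, Y) = ||Xbar - Ybar||_2 / sqrt(s2_X / F + s2_Y / M)
##   s2_X = sum_i ||X_i - Xbar||_2^2 / (F - 1)      (likewise s2_Y)
##
## where X (genes x F) holds the female samples, Y (genes x M) the male
## samples, Xbar/Ybar are genewise means, and norms run over genes.
## Because sex groups are imbalanced, both a "true" distribution
## (subsamples with correct labels) and a "null" distribution
## (subsamples with randomly assigned labels) are built from repeated
## equal-size draws.

#' Transcriptome-wide signal-to-noise ratio
#'
#' @param X Expression matrix (genes x F) for the first group (females).
#' @param Y Expression matrix (genes x M) for the second group (males),
#'   same genes.
#' @return A single non-negative number.  Errors if both groups are
#'   constant (zero denominator).
#' @export
compute_snr <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stopf("X and Y must share the gene axis")
  F_ <- ncol(X); M_ <- ncol(Y)
  if (F_ < 2L || M_ < 2L) stopf("need >= 2 samples per group (got F=%d, M=%d)", F_, M_)
  xbar <- rowMeans(X)
  ybar <- rowMeans(Y)
  s2x <- sum((X - xbar)^2) / (F_ - 1)
  s2y <- sum((Y - ybar)^2) / (M_ - 1)
  denom <- sqrt(s2x / F_ + s2y / M_)
  if (denom == 0) stopf("SNR undefined: both groups are constant (zero variance)")
  sqrt(sum((xbar - ybar)^2)) / denom
}

#' Per-iteration subsample sizes for the SNR distributions
#'
#' `n_per_sex = floor(rate * min(F, M))` samples of each sex are drawn
#' per "true" iteration, and `2 * n_per_sex` samples in total per "null"
#' iteration (then split into two arbitrary pseudo-sex groups).  For a
#' region with 100 females and 200 males at the default 90% rate this
#' gives 90 per sex and 180 per null draw.
#'
#' @param F_,M_ Female and male group sizes.
#' @param rate Subsampling rate in (0, 1].
#' @return List with `n_per_sex` and `n_null_total`.
#' @export
subsample_size <- function(F_, M_, rate = 0.90) {
  check_count(F_, "F_", lower = 2L)
  check_count(M_, "M_", lower = 2L)
  check_number(rate, "rate", lower = 0, upper = 1, strict_lower = TRUE)
  n <- as.integer(floor(rate * min(F_, M_)))
  if (n < 2L) stopf("subsample size %d < 2: variance undefined (F=%d, M=%d, rate=%g)", n, F_, M_, rate)
  list(n_per_sex = n, n_null_total = 2L * n)
}

#' SNR analysis configuration
#'
#' @param n_iterations Number of subsampled draws per distribution.
#' @param subsample_rate Fraction of the smaller sex group drawn per sex
#'   per iteration.
#' @param comparison How the empirical P is computed: `"paired"`
#'   (default) is the per-iteration fraction of null draws exceeding the
#'   true draw with the same index; `"vs_true_mean"` is the fraction of
#'   null draws exceeding the mean of the true distribution.
#' @param seed Integer seed.
#' @return List of class `"snr_config"`.
#' @export
snr_config <- function(n_iterations = 10000, subsample_rate = 0.90,
                       comparison = c("paired", "vs_true_mean"),
                       seed = 1L) {
  structure(list(
    n_iterations = check_count(n_iterations, "n_iterations", lower = 1L),
    subsample_rate = check_number(subsample_rate, "subsample_rate",
                                  lower = 0, upper = 1, strict_lower = TRUE),
    comparison = match.arg(comparison),
    seed = check_count(seed, "seed")
  ), class = "snr_config")
}

#' Subsampled true/null SNR distributions for one region
#'
#' Draws `n_iterations` "true" SNR values (equal-size per-sex subsamples
#' with correct labels) and `n_iterations` "null" values (2n samples
#' drawn regardless of sex and split into two arbitrary pseudo-sex
#' groups), compares the distributions by a two-sided Wilcoxon rank-sum
#' test, and reports the empirical P
#' `P = (SNR_null > SNR_true) / n_iterations` under the configured
#' comparison rule.
#'
#' @param expr Expression matrix (genes x samples), e.g. logCPM, raw or
#'   covariate-adjusted.
#' @param samples Sample table with `sample_id`, `sex`
#'   ("Female"/"Male") and `region` columns; columns of `expr` must
#'   match `sample_id`.
#' @param region Region to analyse.
#' @param config An [snr_config()].
#' @return Object of class `"snr_result"`: `true_draws`, `null_draws`,
#'   `mean_true`, `mean_null`, `wilcoxon_p`, `empirical_p`, `F`, `M`,
#'   `n`, `region`.
#' @export
run_snr_analysis <- function(expr, samples, region, config = snr_config()) {
  stopifnot(is.data.frame(samples), all(c("sex", "region") %in% names(samples)))
  in_region <- samples$region == region
  if (!any(in_region)) stopf("region '%s' has no samples", region)
  expr <- as.matrix(expr)
  if (!is.null(samples$sample_id) && !is.null(colnames(expr))) {
    expr <- expr[, match(samples$sample_id, colnames(expr)), drop = FALSE]
  }
  e <- expr[, in_region, drop = FALSE]
  sex <- samples$sex[in_region]
  f_idx <- which(sex == "Female")
  m_idx <- which(sex == "Male")
  F_ <- length(f_idx); M_ <- length(m_idx)
  if (F_ < 3L || M_ < 3L) {
    stopf("region '%s' too small: %d female / %d male samples", region, F_, M_)
  }
  ss <- subsample_size(F_, M_, config$subsample_rate)
  n <- ss$n_per_sex
  set.seed(config$seed)
  it <- config$n_iterations
  true_draws <- numeric(it)
  null_draws <- numeric(it)
  all_idx <- seq_len(ncol(e))
  for (i in seq_len(it)) {
    fi <- f_idx[sample.int(F_, n)]
    mi <- m_idx[sample.int(M_, n)]
    true_draws[i] <- compute_snr(e[, fi, drop = FALSE], e[, mi, drop = FALSE])
    pool <- sample(all_idx, 2L * n)
    null_draws[i] <- compute_snr(e[, pool[seq_len(n)], drop = FALSE],
                                 e[, pool[n + seq_len(n)], drop = FALSE])
  }
  wp <- if (it >= 2L) {
    suppressWarnings(wilcox.test(true_draws, null_draws)$p.value)
  } else NA_real_
  emp <- switch(config$comparison,
                paired = mean(null_draws > true_draws),
                vs_true_mean = mean(null_draws > mean(true_draws)))
  structure(list(true_draws = true_draws, null_draws = null_draws,
                 mean_true = mean(true_draws), mean_null = mean(null_draws),
                 wilcoxon_p = wp, empirical_p = emp,
                 F = F_, M = M_, n = n, region = region,
                 comparison = config$comparison),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("SNR analysis: region %s (F=%d, M=%d, n=%d per sex)\n",
              x$region, x$F, x$M, x$n))
  cat(sprintf("  mean true SNR %.3f, mean null SNR %.3f\n",
              x$mean_true, x$mean_null))
  cat(sprintf("  Wilcoxon p = %.3g, empirical P = %.4g (%s)\n",
              x$wilcoxon_p, x$empirical_p, x$comparison))
  invisible(x)
}

#' Summarise SNR results across regions as a table
#'
#' @param results List of `"snr_result"` objects.
#' @return data.frame with one row per region.
#' @export
snr_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    data.frame(region = x$region, F = x$F, M = x$M, n = x$n,
               mean_true = x$mean_true, mean_null = x$mean_null,
               wilcoxon_p = x$wilcoxon_p, empirical_p = x$empirical_p,
               stringsAsFactors = FALSE)
  }))
}
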