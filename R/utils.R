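## Internal helpers shared across modules.

#' @importFrom stats rnorm rbinom runif rnbinom rgamma quantile var sd
#'   pchisq qnorm pnorm dhyper phyper p.adjust lm.fit wilcox.test cor
#'   ks.test fisher.test median rmultinom setNames aggregate
#' @importFrom utils head read.delim write.table
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("'%s' must be TRUE or FALSE", name)
  }
  x
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stopf("'%s' must be > %g (got %g)", name, lower, x)
  }
  if (x < lower || x > upper) {
    stopf("'%s' must be in [%g, %g] (got %g)", name, lower, upper, x)
  }
  x
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) stopf("'%s' must be an integer (got %g)", name, x)
  as.integer(x)
}

check_proportion <- function(x, name) check_number(x, name, 0, 1)

## Derive a reproducible 32-bit sub-seed from a global seed and a stage
## label, so stages are independently reproducible under one pipeline seed.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

## Counts-per-million on raw or effective library sizes.
cpm_matrix <- function(counts, lib_size = colSums(counts)) {
  sweep(counts, 2L, lib_size / 1e6, "/")
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Percentage of differentially expressed genes
#'
#' Reporting helper: the share of analysed genes called DE, as a
#' percentage rounded the way results tables print it.
#'
#' @param n_de Number of DE genes.
#' @param n_total Number of analysed genes.
#' @param digits Decimal places.
#' @return A percentage (e.g. 6.1).
#' @export
deg_percentage <- function(n_de, n_total, digits = 1) {
  round(100 * n_de / n_total, digits)
}
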