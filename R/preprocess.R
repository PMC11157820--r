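## Sample exclusion, low-expression filtering, TMM scaling, logCPM.

#' Remove samples from donors flagged for exclusion
#'
#' Drops every sample whose donor is coded `"positive"` or `"unknown"`
#' on any of the given exclusion fields (e.g. brain-related or systemic
#' disease status).  Only donors explicitly `"negative"` on every field
#' survive.
#'
#' @param samples data.frame with a `donor` column and one column per
#'   exclusion field, values in `{"positive","negative","unknown"}`.
#' @param exclusion_fields Character vector of column names to screen.
#' @return The filtered sample table, with an attribute
#'   `"removed_per_field"` (named integer vector of samples removed per
#'   field, overlapping fields counted independently).
#' @export
exclude_samples <- function(samples, exclusion_fields) {
  stopifnot(is.data.frame(samples))
  missing_f <- setdiff(exclusion_fields, names(samples))
  if (length(missing_f)) {
    stopf("exclusion fields not in sample table: %s",
          paste(missing_f, collapse = ", "))
  }
  if (length(exclusion_fields) == 0L) return(samples)
  bad <- rep(FALSE, nrow(samples))
  removed <- integer(length(exclusion_fields))
  names(removed) <- exclusion_fields
  for (f in exclusion_fields) {
    v <- as.character(samples[[f]])
    ok_vals <- v %in% c("positive", "negative", "unknown")
    if (!all(ok_vals)) {
      stopf("field '%s' has values outside {positive, negative, unknown}", f)
    }
    hit <- v %in% c("positive", "unknown")
    removed[f] <- sum(hit)
    bad <- bad | hit
  }
  ## exclusion is donor-level: any flagged sample removes the whole donor
  bad_donors <- unique(samples$donor[bad])
  keep <- !(samples$donor %in% bad_donors)
  if (!any(keep)) stopf("all samples excluded")
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_per_field") <- removed
  out
}

#' Filter low-expression genes by a CPM threshold in a minimum number of samples
#'
#' A gene is retained iff its raw (pre-scaling) CPM exceeds
#' `cpm_cutoff` in at least `ceiling(group_fraction * min(group_sizes))`
#' samples.  With the cohort's smallest group of 27 samples and the
#' default 70% fraction this reproduces the 19-sample rule.
#'
#' @param counts genes x samples count matrix.
#' @param group_sizes Named or unnamed integer vector of group sizes
#'   (e.g. samples per sex-region group); the smallest determines the
#'   threshold.
#' @param cpm_cutoff CPM that must be exceeded (strictly, by default).
#' @param group_fraction Fraction of the smallest group size.
#' @param strict Use strict `>` (default) or `>=` on the CPM cutoff.
#' @return Logical vector (one per gene) with attribute
#'   `"min_samples"`, the computed sample threshold.
#' @export
filter_low_expression <- function(counts, group_sizes, cpm_cutoff = 10,
                                  group_fraction = 0.70, strict = TRUE) {
  if (length(group_sizes) == 0L || any(group_sizes < 1)) {
    stopf("'group_sizes' must be non-empty with all sizes >= 1")
  }
  check_number(cpm_cutoff, "cpm_cutoff", lower = 0)
  check_proportion(group_fraction, "group_fraction")
  min_samples <- as.integer(ceiling(group_fraction * min(group_sizes)))
  cpm <- cpm_matrix(counts)
  hits <- if (strict) cpm > cpm_cutoff else cpm >= cpm_cutoff
  mask <- rowSums(hits) >= min_samples
  attr(mask, "min_samples") <- min_samples
  mask
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Computes per-sample TMM normalisation factors: a weighted trimmed
#' mean of gene-wise log-ratios (M) against a reference sample, doubly
#' trimmed on M and on average abundance (A), with inverse-variance
#' (delta-method) weights, rescaled to geometric mean 1.  The reference
#' is the sample whose upper-quartile count fraction is closest to the
#' cross-sample mean.  Computation is delegated to
#' [edgeR::calcNormFactors()].
#'
#' @param counts genes x samples count matrix (>= 2 samples, positive
#'   library sizes).
#' @param trim_M,trim_A Trim fractions on the log-ratio and abundance
#'   scales.
#' @return A list of class `"normalization_result"` with
#'   `norm_factors`, `lib_size` (raw), `effective_lib_size`
#'   (`lib_size * norm_factors`).
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  if (ncol(counts) < 2L) stopf("TMM needs >= 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stopf("every sample must have a positive library size")
  nf <- edgeR::calcNormFactors(counts, method = "TMM",
                               logratioTrim = trim_M, sumTrim = trim_A)
  if (any(!is.finite(nf))) {
    stopf("TMM factor undefined: a sample shares no positively expressed gene with the reference")
  }
  nf <- nf / geometric_mean(nf)
  structure(list(norm_factors = nf, lib_size = lib,
                 effective_lib_size = lib * nf),
            class = "normalization_result")
}

#' Moderated log2 counts-per-million
#'
#' `log2((count + prior_count) / (effective_library_size + 1) * 1e6)`.
#'
#' @param counts genes x samples count matrix.
#' @param effective_lib_size Positive per-sample effective library sizes
#'   (raw library size times TMM factor); defaults to raw library sizes.
#' @param prior_count Non-negative prior count added to every entry.
#' @return Real matrix of the same shape.
#' @export
log_cpm <- function(counts, effective_lib_size = colSums(counts),
                    prior_count = 0.5) {
  check_number(prior_count, "prior_count", lower = 0)
  if (any(effective_lib_size <= 0)) {
    stopf("effective library sizes must be positive")
  }
  log2(sweep(counts + prior_count, 2L, (effective_lib_size + 1) / 1e6, "/"))
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("TMM normalization for", length(x$norm_factors), "samples\n")
  cat("  norm factor range:",
      sprintf("%.4f .. %.4f", min(x$norm_factors), max(x$norm_factors)), "\n")
  invisible(x)
}
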