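## Group-means differential expression with precision weights, surrogate
## covariates, donor blocking, per-region and omnibus sex contrasts,
## empirical-Bayes moderation and BH FDR.
##
## The model is a single dataset-wide group-means fit,
##   ~ 0 + SEX_REGION + SV1 + ... + SVk   with donor as a random effect,
## from which each region's female-minus-male contrast and an omnibus
## contrast (the equal-weight average of the region contrasts) are
## extracted.  Positive logFC always means higher expression in females.

#' Build the sex-by-region group-means design
#'
#' @param samples Sample table with `sex` ("Female"/"Male"), `region`
#'   and `donor` columns.
#' @param covariates Optional numeric matrix (samples x k) of fixed-effect
#'   covariates (e.g. surrogate variables).
#' @return List with `design` (full-rank model matrix, group columns
#'   first), `group` (factor, levels "Sex_Region"), `donors`, and
#'   `group_levels`.
#' @export
make_design <- function(samples, covariates = NULL) {
  stopifnot(all(c("sex", "region") %in% names(samples)))
  if (!all(samples$sex %in% c("Female", "Male"))) {
    stopf("'sex' must be coded Female/Male")
  }
  group <- factor(paste(samples$sex, samples$region, sep = "_"))
  design <- stats::model.matrix(~ 0 + group)
  colnames(design) <- levels(group)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(samples)) {
      stopf("covariates must have one row per sample")
    }
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("SV", seq_len(ncol(covariates)))
    }
    design <- cbind(design, covariates)
  }
  if (qr(design)$rank < ncol(design)) {
    stopf("design matrix is rank deficient")
  }
  list(design = design, group = group,
       donors = samples$donor, group_levels = levels(group))
}

#' Estimate surrogate covariates by residual SVD with parallel analysis
#'
#' Residualises the expression matrix on the full model, takes the
#' leading right singular vectors of the residuals as candidate latent
#' covariates, and retains the components whose singular values exceed
#' the 95th percentile of singular values obtained after independently
#' permuting each gene's residuals (parallel analysis).  Alternatively a
#' fixed number of components can be requested, mirroring analyses that
#' pre-specify the surrogate-variable count.
#'
#' @param logcpm Expression matrix (genes x samples).
#' @param design Full model matrix (samples x p).
#' @param n_max Maximum number of components returned (>= 0).
#' @param n_sv Optional fixed number of components (overrides the
#'   permutation test).
#' @param n_perm Number of permutations for parallel analysis.
#' @param quantile_cut Null quantile a singular value must exceed; the
#'   default 1 is the strict max rule, appropriate for small permutation
#'   counts.
#' @param seed Integer seed for the permutations.
#' @return Numeric matrix (samples x k, 0 <= k <= n_max) with columns
#'   SV1..SVk; a zero-column matrix when nothing passes.
#' @export
estimate_surrogate_covariates <- function(logcpm, design, n_max = 10,
                                          n_sv = NULL, n_perm = 20,
                                          quantile_cut = 1, seed = 1L) {
  n_max <- check_count(n_max, "n_max", lower = 0L)
  logcpm <- as.matrix(logcpm)
  S <- ncol(logcpm)
  if (nrow(design) != S) stopf("design must have one row per sample")
  resid <- t(stats::lm.fit(design, t(logcpm))$residuals)
  if (n_max == 0L) {
    return(matrix(numeric(0), S, 0))
  }
  sv <- svd(resid, nu = 0, nv = min(n_max, S - 1L))
  d_obs <- sv$d[seq_len(min(n_max, length(sv$d)))]
  if (is.null(n_sv)) {
    set.seed(check_count(seed, "seed"))
    k_eval <- length(d_obs)
    d_null <- matrix(0, n_perm, k_eval)
    for (b in seq_len(n_perm)) {
      perm <- t(apply(resid, 1L, sample))
      d_null[b, ] <- svd(perm, nu = 0, nv = 0)$d[seq_len(k_eval)]
    }
    thresh <- apply(d_null, 2L, quantile, probs = quantile_cut, names = FALSE)
    pass <- d_obs > thresh
    k <- if (all(pass)) k_eval else (which(!pass)[1] - 1L)
  } else {
    k <- min(check_count(n_sv, "n_sv", lower = 0L), n_max, ncol(sv$v))
  }
  if (k == 0L) return(matrix(numeric(0), S, 0))
  out <- sv$v[, seq_len(k), drop = FALSE]
  colnames(out) <- paste0("SV", seq_len(k))
  out
}

#' Precision weights and sample quality weights (voom-style)
#'
#' Fits the mean-variance trend of log-CPM (lowess of sqrt residual SD
#' against average log-count), converts predicted standard deviations
#' into inverse-variance observation weights, and estimates per-sample
#' quality weights from sample-wise residual dispersion relative to the
#' trend.  Quality weights are bounded to [0.1, 10] and normalised to
#' geometric mean 1; the final weight of an observation is the product
#' of the two.  Computation is delegated to [limma::voom()] and
#' [limma::arrayWeights()].
#'
#' @param counts genes x samples count matrix (post-filtering).
#' @param norm A `"normalization_result"` from [tmm_factors()], or NULL
#'   to use raw library sizes.
#' @param design Model matrix.
#' @param span Lowess span of the mean-variance trend.
#' @return List: `logcpm`, `obs_weights`, `sample_weights`, `weights`
#'   (the product, genes x samples).
#' @export
voom_transform <- function(counts, norm = NULL, design, span = 0.5) {
  if (ncol(counts) <= ncol(design)) {
    stopf("fewer samples (%d) than residual df allows for %d design columns",
          ncol(counts), ncol(design))
  }
  lib <- if (is.null(norm)) colSums(counts) else norm$effective_lib_size
  v <- limma::voom(counts, design, lib.size = lib, span = span)
  aw <- limma::arrayWeights(v, design)
  aw <- pmin(pmax(aw, 0.1), 10)
  aw <- aw / geometric_mean(aw)
  w <- sweep(v$weights, 2L, aw, "*")
  dimnames(w) <- dimnames(v$E)
  list(logcpm = v$E, obs_weights = v$weights, sample_weights = aw,
       weights = w)
}

#' Consensus intra-donor correlation
#'
#' Estimates, per gene, the residual correlation between repeated
#' samples of the same donor and combines them into one consensus value
#' via the hyperbolic tangent of the trimmed mean of atanh-transformed
#' per-gene correlations (delegated to [limma::duplicateCorrelation()]).
#'
#' @param logcpm Expression matrix (genes x samples).
#' @param design Model matrix.
#' @param donors Donor identifier per sample.
#' @param weights Optional observation weights.
#' @return Consensus correlation, strictly inside (-1, 1).
#' @export
estimate_duplicate_correlation <- function(logcpm, design, donors,
                                           weights = NULL) {
  tab <- table(donors)
  if (!any(tab >= 2L)) {
    stopf("no donor contributes >= 2 samples; refit with correlation = 0 instead of donor blocking")
  }
  dc <- limma::duplicateCorrelation(logcpm, design, block = donors,
                                    weights = weights)
  rho <- dc$consensus.correlation
  max(min(rho, 1 - 1e-8), -1 + 1e-8)
}

#' Female-minus-male region contrasts plus the omnibus contrast
#'
#' Each region column carries +1 on that region's female group and -1
#' on its male group; the omnibus column is the elementwise mean of the
#' region columns, i.e. entries of magnitude 1/n_regions.
#'
#' @param group_levels Character vector of "Sex_Region" group names (the
#'   group columns of the design).
#' @param design_colnames Optional full design column names; contrast
#'   rows for non-group columns (covariates) are zero.
#' @return Contrast matrix with one column per region plus "Omnibus".
#' @export
make_sex_region_contrasts <- function(group_levels,
                                      design_colnames = group_levels) {
  parts <- strsplit(group_levels, "_", fixed = TRUE)
  sex <- vapply(parts, `[[`, "", 1L)
  region <- vapply(parts, function(p) paste(p[-1], collapse = "_"), "")
  regions <- sort(unique(region))
  cm <- matrix(0, length(design_colnames), length(regions) + 1L,
               dimnames = list(design_colnames, c(regions, "Omnibus")))
  for (r in regions) {
    f <- group_levels[sex == "Female" & region == r]
    m <- group_levels[sex == "Male" & region == r]
    if (length(f) != 1L || length(m) != 1L) {
      stopf("region '%s' lacks a Female or Male group", r)
    }
    cm[f, r] <- 1
    cm[m, r] <- -1
  }
  cm[, "Omnibus"] <- rowMeans(cm[, regions, drop = FALSE])
  cm
}

#' Fit per-gene models and extract contrasts
#'
#' Generalised least squares per gene under a block-equicorrelated (by
#' donor) covariance with the consensus correlation and the given
#' observation weights, via [limma::lmFit()] and
#' [limma::contrasts.fit()].
#'
#' @param logcpm Expression matrix (genes x samples).
#' @param design Model matrix.
#' @param contrasts Contrast matrix (design columns x contrasts).
#' @param weights Optional observation weights.
#' @param donors Optional donor blocking vector.
#' @param correlation Consensus intra-donor correlation (used only with
#'   `donors`).
#' @return An [limma::MArrayLM-class] fit on the contrast scale.
#' @export
fit_gene_models <- function(logcpm, design, contrasts, weights = NULL,
                            donors = NULL, correlation = 0) {
  if (nrow(contrasts) != ncol(design)) {
    stopf("contrast matrix rows must match design columns")
  }
  fit <- if (!is.null(donors) && correlation != 0) {
    limma::lmFit(logcpm, design, weights = weights, block = donors,
                 correlation = correlation)
  } else {
    limma::lmFit(logcpm, design, weights = weights)
  }
  limma::contrasts.fit(fit, contrasts)
}

#' Empirical-Bayes moderation and per-contrast BH FDR
#'
#' Squeezes the per-gene residual variances toward a common prior by
#' moment-matching the distribution of log residual variances to a
#' scaled-F law ([limma::eBayes()]), forms moderated t-statistics with
#' augmented degrees of freedom, and BH-adjusts p-values within each
#' contrast separately.
#'
#' @param fit Contrast-scale fit from [fit_gene_models()].
#' @param gene_annotation Optional data.frame with `gene_id` and
#'   `chromosome` (and optionally `par`) to annotate the output.
#' @return A `"de_table"` data.frame: gene_id, chromosome, contrast,
#'   logFC, AveExpr, t, P.Value, adj.P.Val.  Positive logFC = higher in
#'   females.
#' @export
moderate_and_test <- function(fit, gene_annotation = NULL) {
  if (nrow(fit$coefficients) < 10L) stopf("need >= 10 genes for moderation")
  if (all(fit$sigma == 0, na.rm = TRUE)) {
    stopf("all residual variances are zero")
  }
  eb <- limma::eBayes(fit)
  contrast_names <- colnames(eb$coefficients)
  gene_id <- rownames(eb$coefficients)
  if (is.null(gene_id)) gene_id <- sprintf("gene%05d", seq_len(nrow(eb)))
  out <- do.call(rbind, lapply(contrast_names, function(cn) {
    tt <- limma::topTable(eb, coef = cn, number = Inf, sort.by = "none")
    data.frame(gene_id = gene_id, contrast = cn, logFC = tt$logFC,
               AveExpr = tt$AveExpr, t = tt$t, P.Value = tt$P.Value,
               adj.P.Val = tt$adj.P.Val, stringsAsFactors = FALSE)
  }))
  if (!is.null(gene_annotation)) {
    m <- match(out$gene_id, gene_annotation$gene_id)
    out$chromosome <- gene_annotation$chromosome[m]
    if (!is.null(gene_annotation$par)) out$par <- gene_annotation$par[m]
  } else {
    out$chromosome <- NA_character_
  }
  rownames(out) <- NULL
  attr(out, "df_prior") <- eb$df.prior
  attr(out, "s2_prior") <- eb$s2.prior
  class(out) <- c("de_table", "data.frame")
  out
}

#' End-to-end differential expression for one dataset
#'
#' Convenience orchestrator: TMM scaling, logCPM, surrogate-covariate
#' estimation on the group-residualised matrix, voom precision and
#' sample quality weights, consensus donor correlation, the group-means
#' GLS fit, region + omnibus contrasts, and empirical-Bayes testing.
#'
#' @param counts Filtered genes x samples count matrix.
#' @param samples Sample table (`sample_id`, `donor`, `sex`, `region`).
#' @param genes Gene annotation (gene_id, chromosome, par).
#' @param n_sv Number of surrogate variables: NULL for the parallel
#'   analysis decision, an integer to fix the count, 0 for none.
#' @param n_sv_max Cap on estimated surrogate variables.
#' @param block_donor Estimate and use the consensus donor correlation.
#' @param seed Seed for the surrogate-variable permutation test.
#' @return List: `de` (the `"de_table"`), `fit`, `rho`, `svs`, `voom`,
#'   `norm`, `contrasts`.
#' @export
run_de_analysis <- function(counts, samples, genes = NULL, n_sv = NULL,
                            n_sv_max = 10, block_donor = TRUE, seed = 1L) {
  norm <- tmm_factors(counts)
  d0 <- make_design(samples)
  logcpm0 <- log_cpm(counts, norm$effective_lib_size)
  svs <- estimate_surrogate_covariates(logcpm0, d0$design, n_max = n_sv_max,
                                       n_sv = n_sv, seed = seed)
  d <- make_design(samples, covariates = if (ncol(svs)) svs else NULL)
  v <- voom_transform(counts, norm, d$design)
  rho <- 0
  if (block_donor && any(table(samples$donor) >= 2L)) {
    rho <- estimate_duplicate_correlation(v$logcpm, d$design, d$donors,
                                          weights = v$weights)
  }
  cm <- make_sex_region_contrasts(d$group_levels, colnames(d$design))
  fit <- fit_gene_models(v$logcpm, d$design, cm, weights = v$weights,
                         donors = if (block_donor) d$donors else NULL,
                         correlation = rho)
  de <- moderate_and_test(fit, gene_annotation = genes)
  list(de = de, fit = fit, rho = rho, svs = svs, voom = v, norm = norm,
       contrasts = cm)
}
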