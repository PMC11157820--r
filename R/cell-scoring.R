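## Weighted per-cell gene-set scoring with expression-matched control
## gene sets, per-cell empirical p-values, and group-level enrichment
## and heterogeneity tests for single-nucleus data.

#' Build a Z-weighted gene set from a DE table
#'
#' Takes the autosomal genes with logFC of the requested sign, ranks
#' them by significance, keeps the top `top_n`, and assigns each a
#' weight equal to the Z-normalised DE significance
#' (`qnorm(p / 2, lower.tail = FALSE)`, capped).
#'
#' @param de Per-gene DE table (`gene_id`, `logFC`, `P.Value`,
#'   `chromosome`).
#' @param direction `"female_up"` (logFC > 0) or `"male_up"`
#'   (logFC < 0).
#' @param top_n Maximum set size.
#' @param z_cap Cap on the Z weights (guards p = 0).
#' @return List of class `"weighted_gene_set"`: `genes`, `weights`,
#'   `direction`.
#' @export
build_weighted_geneset <- function(de, direction = c("female_up", "male_up"),
                                   top_n = 1000, z_cap = 10) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "logFC", "P.Value", "chromosome") %in% names(de)))
  top_n <- check_count(top_n, "top_n", lower = 1L)
  auto <- !(de$chromosome %in% c("chrX", "chrY"))
  keep <- auto & if (direction == "female_up") de$logFC > 0 else de$logFC < 0
  tab <- de[keep, , drop = FALSE]
  if (nrow(tab) < 10L) stopf("fewer than 10 eligible autosomal genes for direction '%s'", direction)
  tab <- tab[order(tab$P.Value), , drop = FALSE]
  tab <- head(tab, top_n)
  z <- qnorm(pmax(tab$P.Value, 1e-300) / 2, lower.tail = FALSE)
  structure(list(genes = tab$gene_id, weights = pmin(z, z_cap),
                 direction = direction),
            class = "weighted_gene_set")
}

## Joint equal-occupancy (mean, variance) bin label per gene.
mean_var_bins <- function(m, v, n_bins_mean, n_bins_var) {
  cut_eq <- function(x, k) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1L),
                          names = FALSE))
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  mb <- cut_eq(m, n_bins_mean)
  vb <- integer(length(v))
  for (b in unique(mb)) {
    i <- mb == b
    vb[i] <- cut_eq(v[i], min(n_bins_var, sum(i)))
  }
  paste(mb, vb, sep = ".")
}

#' Score cells for a weighted gene set against matched control sets
#'
#' The raw score of a cell is the weighted mean of its log1p-CPM
#' expression over the set genes.  `n_ctrl` control gene sets are drawn
#' by replacing each set gene with a random gene from the same joint
#' (mean, variance) expression bin (keeping the weight), and scored the
#' same way for every cell.  The per-cell empirical p is
#' `(1 + #\{control score >= raw score\}) / (n_ctrl + 1)`; the
#' normalised score is `(raw - control mean) / control SD`.
#'
#' Cells with fewer than `min_genes_per_cell` detected genes and genes
#' detected in fewer than `min_cell_fraction` of cells are dropped
#' before scoring.
#'
#' @param expr genes x cells count matrix (rownames = gene ids).
#' @param gene_set A `"weighted_gene_set"`; at least half its genes
#'   must be present in `expr` after filtering.
#' @param n_ctrl Number of control gene sets.
#' @param n_bins_mean,n_bins_var Equal-occupancy bins on gene mean and
#'   (within mean bin) variance.
#' @param min_genes_per_cell,min_cell_fraction Pre-filtering thresholds.
#' @param seed Integer seed.
#' @return List of class `"cell_score_result"`: `cell_id`, `raw`,
#'   `normalized`, `empirical_p`, `control_scores` (cells x n_ctrl),
#'   `control_norm` (control scores normalised per cell), `n_ctrl`.
#' @export
score_cells <- function(expr, gene_set, n_ctrl = 1500,
                        n_bins_mean = 10, n_bins_var = 10,
                        min_genes_per_cell = 250, min_cell_fraction = 0.01,
                        seed = 1L) {
  stopifnot(inherits(gene_set, "weighted_gene_set"))
  n_ctrl <- check_count(n_ctrl, "n_ctrl", lower = 1L)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stopf("expr needs gene rownames")
  detected <- colSums(expr > 0)
  expr <- expr[, detected >= min_genes_per_cell, drop = FALSE]
  if (ncol(expr) == 0L) stopf("no cells pass the detected-gene filter")
  gene_det <- rowMeans(expr > 0)
  expr <- expr[gene_det >= min_cell_fraction, , drop = FALSE]

  present <- gene_set$genes %in% rownames(expr)
  if (mean(present) < 0.5) {
    stopf("only %.0f%% of set genes present in the expression matrix (need >= 50%%)",
          100 * mean(present))
  }
  genes <- gene_set$genes[present]
  weights <- gene_set$weights[present]

  lognorm <- log1p(sweep(expr, 2L, colSums(expr) / 1e6, "/"))
  gm <- rowMeans(lognorm)
  gv <- rowSums((lognorm - gm)^2) / (ncol(lognorm) - 1L)
  bins <- mean_var_bins(gm, gv, n_bins_mean, n_bins_var)
  names(bins) <- rownames(lognorm)
  pool_by_bin <- split(rownames(lognorm), bins)

  ## all-zero weights give identically zero scores (weighted sums)
  wsum <- if (sum(weights) > 0) sum(weights) else 1
  raw <- as.numeric(crossprod(lognorm[genes, , drop = FALSE], weights)) / wsum

  set.seed(check_count(seed, "seed"))
  set_bins <- bins[genes]
  ## sample all controls per set gene at once: an n_genes x n_ctrl matrix
  ctrl_genes <- matrix("", length(genes), n_ctrl)
  for (b in unique(set_bins)) {
    idx <- which(set_bins == b)
    pool <- pool_by_bin[[b]]
    if (length(pool) < 2L) {
      stopf("empty or singleton (mean, variance) bin '%s'; use fewer bins", b)
    }
    ctrl_genes[idx, ] <- sample(pool, length(idx) * n_ctrl, replace = TRUE)
  }
  ## all control scores at once: one sparse weight matrix (genes x sets)
  W <- Matrix::sparseMatrix(
    i = match(as.vector(ctrl_genes), rownames(lognorm)),
    j = rep(seq_len(n_ctrl), each = length(genes)),
    x = rep(weights, n_ctrl),
    dims = c(nrow(lognorm), n_ctrl))
  ctrl <- as.matrix(Matrix::crossprod(lognorm, W)) / wsum
  cmean <- rowMeans(ctrl)
  csd <- sqrt(rowSums((ctrl - cmean)^2) / (n_ctrl - 1L))
  csd[csd == 0] <- NA_real_
  normalized <- (raw - cmean) / csd
  emp_p <- (1 + rowSums(ctrl >= raw)) / (n_ctrl + 1)
  control_norm <- (ctrl - cmean) / csd
  structure(list(cell_id = colnames(lognorm), raw = raw,
                 normalized = normalized, empirical_p = emp_p,
                 control_scores = ctrl, control_norm = control_norm,
                 n_ctrl = n_ctrl),
            class = "cell_score_result")
}

#' @export
print.cell_score_result <- function(x, ...) {
  cat(sprintf("Cell scores for %d cells (%d control sets)\n",
              length(x$raw), x$n_ctrl))
  cat(sprintf("  normalized score mean %.3f, %d cells with empirical p < 0.05\n",
              mean(x$normalized, na.rm = TRUE),
              sum(x$empirical_p < 0.05)))
  invisible(x)
}

#' Group-level enrichment and heterogeneity tests of cell scores
#'
#' For each pre-labelled group of cells (cell type, cortical layer,
#' ...), enrichment is a Monte-Carlo test of the group's standardised
#' mean score -- the deviation of the group mean from the all-cell
#' mean, divided by the cross-cell SD of that score set -- against the
#' same statistic recomputed from the normalised control-score table;
#' heterogeneity is the analogous test on the within-group variance of
#' normalised scores.  Each Monte-Carlo draw pairs one control gene
#' set with a freshly resampled cell group of the same size, so the
#' null carries both gene-sampling and cell-sampling variability.
#' These choices matter: without centring and per-set standardisation,
#' a gene set with any global association fluctuates more across cells
#' than its control sets do and would flag every group, including
#' randomly relabelled ones.  P-values use the add-one correction and
#' are Bonferroni-corrected across groups.
#'
#' @param scores A `"cell_score_result"` from [score_cells()].
#' @param labels Group label per scored cell (same order as
#'   `scores$cell_id`).
#' @param min_group_size Groups below this size are skipped with a
#'   warning.
#' @param seed Seed for the membership resampling.
#' @return data.frame: group, n_cells, mean_score, enrichment_p,
#'   heterogeneity_p, enrichment_p_bonf, heterogeneity_p_bonf,
#'   frac_sig_cells.
#' @export
group_tests <- function(scores, labels, min_group_size = 20, seed = 1L) {
  stopifnot(inherits(scores, "cell_score_result"))
  if (length(labels) != length(scores$cell_id)) {
    stopf("one label per scored cell required")
  }
  labels <- as.character(labels)
  groups <- unique(labels)
  keep <- vapply(groups, function(g) sum(labels == g) >= min_group_size,
                 TRUE)
  if (any(!keep)) {
    warning(sprintf("skipping groups below %d cells: %s", min_group_size,
                    paste(groups[!keep], collapse = ", ")), call. = FALSE)
  }
  groups <- groups[keep]
  cn <- scores$control_norm
  ok <- is.finite(scores$normalized)
  n_all <- sum(ok)
  cn <- cn[ok, , drop = FALSE]
  B <- ncol(cn)
  grand_obs <- mean(scores$normalized[ok])
  sd_obs <- sd(scores$normalized[ok])
  grand_null <- colMeans(cn)
  sd_null <- sqrt(colSums((cn - rep(grand_null, each = n_all))^2) /
                    (n_all - 1L))
  set.seed(check_count(seed, "seed"))
  res <- lapply(groups, function(g) {
    i <- labels == g & ok
    obs_mean <- mean(scores$normalized[i])
    obs_dev <- (obs_mean - grand_obs) / sd_obs
    obs_var <- var(scores$normalized[i])
    null_dev <- numeric(B)
    null_var <- numeric(B)
    for (j in seq_len(B)) {
      rg <- sample.int(n_all, sum(i))
      null_dev[j] <- (mean(cn[rg, j]) - grand_null[j]) / sd_null[j]
      null_var[j] <- var(cn[rg, j])
    }
    data.frame(
      group = g, n_cells = sum(i), mean_score = obs_mean,
      enrichment_p = (1 + sum(null_dev >= obs_dev)) / (B + 1),
      heterogeneity_p = (1 + sum(null_var >= obs_var)) / (B + 1),
      frac_sig_cells = mean(scores$empirical_p[i] < 0.05),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  k <- nrow(out)
  out$enrichment_p_bonf <- pmin(out$enrichment_p * k, 1)
  out$heterogeneity_p_bonf <- pmin(out$heterogeneity_p * k, 1)
  attr(out, "n_groups") <- k
  out
}
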