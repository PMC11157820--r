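## Two-study directional meta-analysis: intersect genes, require logFC
## sign concordance, combine p-values (Fisher / adaptively weighted
## Fisher), BH-adjust.

#' Direction-concordance filter across two DE tables
#'
#' Intersects the two tables on gene identifier (within one contrast
#' each) and keeps only genes whose logFC has the same, non-zero sign in
#' both studies.  Genes with logFC exactly 0 in either study have no
#' direction and are dropped.
#'
#' @param table_a,table_b `"de_table"` data.frames (or any data.frame
#'   with `gene_id` and `logFC`), one row per gene.
#' @return Character vector of concordant gene identifiers, with
#'   attribute `"n_dropped_discordant"` and `"n_dropped_zero"`.
#' @export
concordance_filter <- function(table_a, table_b) {
  stopifnot(all(c("gene_id", "logFC") %in% names(table_a)),
            all(c("gene_id", "logFC") %in% names(table_b)))
  common <- intersect(table_a$gene_id, table_b$gene_id)
  if (length(common) == 0L) stopf("no genes shared between the two studies")
  la <- table_a$logFC[match(common, table_a$gene_id)]
  lb <- table_b$logFC[match(common, table_b$gene_id)]
  zero <- la == 0 | lb == 0
  agree <- sign(la) == sign(lb) & !zero
  out <- common[agree]
  attr(out, "n_dropped_discordant") <- sum(!agree & !zero)
  attr(out, "n_dropped_zero") <- sum(zero)
  out
}

## Fisher's combined statistic and chi-square p for a p-value matrix.
fisher_combine <- function(p_matrix) {
  stat <- -2 * rowSums(log(p_matrix))
  pchisq(stat, df = 2 * ncol(p_matrix), lower.tail = FALSE)
}

## Minimum subset-Fisher p over all non-empty binary weight vectors for
## k = 2 studies; ties broken toward the all-ones vector.
aw_min_subset <- function(p_matrix) {
  p1 <- pchisq(-2 * log(p_matrix[, 1]), df = 2, lower.tail = FALSE)
  p2 <- pchisq(-2 * log(p_matrix[, 2]), df = 2, lower.tail = FALSE)
  p12 <- fisher_combine(p_matrix)
  ## column order puts (1,1) first so which.min prefers it on ties
  m <- cbind(p12, p1, p2)
  pick <- max.col(-m, ties.method = "first")
  list(min_p = m[cbind(seq_len(nrow(m)), pick)],
       weights = rbind(c(1, 1), c(1, 0), c(0, 1))[pick, , drop = FALSE])
}

#' Combine two-study p-values by Fisher or adaptively weighted Fisher
#'
#' `method = "fisher"`: the statistic is `-2 * sum(log p)` and the
#' combined p its upper chi-square tail on `2k` degrees of freedom.
#' `method = "aw_fisher"`: per gene, all non-zero binary study-weight
#' vectors are enumerated, the smallest subset-Fisher p is taken as the
#' statistic, and that minimum is calibrated by a shared Monte-Carlo
#' table of the same minimum under independent uniform p-values.  Both
#' combined p-value sets are BH-adjusted.
#'
#' @param p_matrix Numeric matrix, genes x 2 studies, entries in (0, 1].
#' @param method `"fisher"` or `"aw_fisher"`.
#' @param mc_reps Monte-Carlo draws for the aw_fisher calibration.
#' @param seed Seed for the calibration table.
#' @return data.frame (class `"meta_table"`): gene (rownames of
#'   `p_matrix` if present), p_study1, p_study2, weight1, weight2,
#'   combined_p, fdr.
#' @export
combine_pvalues <- function(p_matrix, method = c("fisher", "aw_fisher"),
                            mc_reps = 1e6, seed = 1L) {
  method <- match.arg(method)
  p_matrix <- as.matrix(p_matrix)
  if (any(p_matrix <= 0) || any(p_matrix > 1)) {
    stopf("p-values must lie in (0, 1]; clamp zeros upstream if needed")
  }
  if (method == "aw_fisher" && ncol(p_matrix) != 2L) {
    stopf("aw_fisher supports exactly 2 studies")
  }
  if (method == "fisher") {
    combined <- fisher_combine(p_matrix)
    w <- matrix(1, nrow(p_matrix), ncol(p_matrix))
  } else {
    obs <- aw_min_subset(p_matrix)
    set.seed(check_count(seed, "seed"))
    null_min <- aw_min_subset(matrix(runif(2 * mc_reps), mc_reps, 2))$min_p
    null_sorted <- sort(null_min)
    r <- findInterval(obs$min_p, null_sorted)  # #{null <= obs}
    combined <- (r + 1) / (mc_reps + 1)
    w <- obs$weights
  }
  out <- data.frame(
    gene = if (!is.null(rownames(p_matrix))) rownames(p_matrix)
           else seq_len(nrow(p_matrix)),
    p_study1 = p_matrix[, 1], p_study2 = p_matrix[, 2],
    weight1 = w[, 1], weight2 = w[, 2],
    combined_p = combined,
    fdr = p.adjust(combined, method = "BH"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("meta_table", "data.frame")
  out
}

#' Two-study directional meta-analysis of DE tables
#'
#' Applies the concordance filter, combines the studies' p-values and
#' BH-adjusts, carrying both studies' logFCs through.
#'
#' @param table_a,table_b Per-gene DE tables (single contrast each).
#' @param method,mc_reps,seed Passed to [combine_pvalues()].
#' @return `"meta_table"` data.frame with logFC columns added.
#' @export
meta_analysis <- function(table_a, table_b, method = "aw_fisher",
                          mc_reps = 1e6, seed = 1L) {
  genes <- concordance_filter(table_a, table_b)
  ia <- match(genes, table_a$gene_id)
  ib <- match(genes, table_b$gene_id)
  pm <- cbind(pmax(table_a$P.Value[ia], .Machine$double.xmin),
              pmax(table_b$P.Value[ib], .Machine$double.xmin))
  rownames(pm) <- genes
  out <- combine_pvalues(pm, method = method, mc_reps = mc_reps, seed = seed)
  out$logFC_study1 <- table_a$logFC[ia]
  out$logFC_study2 <- table_b$logFC[ib]
  out
}
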