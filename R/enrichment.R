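## Direction-split gene-set overlap tests, an expression-matched
## permutation null, and logFC-logFC comparison with external tables.

## Two-sided Fisher-exact p from the hypergeometric pmf.  Probabilities
## within a relative tolerance of the observed table's probability are
## counted in the tail (same tie rule as stats::fisher.test).
hyper_two_sided_p <- function(a, size_a, size_b, universe) {
  lo <- max(0L, size_a + size_b - universe)
  hi <- min(size_a, size_b)
  probs <- dhyper(lo:hi, size_a, universe - size_a, size_b)
  sum(probs[probs <= probs[a - lo + 1L] * (1 + 1e-7)])
}

#' Fisher-exact overlap of two gene sets within a universe
#'
#' Genes outside the universe are dropped from both sets before
#' testing.  The odds ratio is the sample odds ratio `ad/bc` of the
#' 2x2 table (a = in both, b = set A only, c = set B only, d =
#' neither), defined as 0 when a = 0; tables with b = 0 or c = 0 give
#' an infinite odds ratio and are flagged as degenerate rather than
#' raising an error.  The two-sided p-value comes from the
#' hypergeometric distribution.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe Character vector of all genes eligible for either
#'   set (must be non-empty).
#' @return List of class `"overlap_result"`: `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `universe_size`, `degenerate`, `n_dropped_a`,
#'   `n_dropped_b`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("empty gene universe")
  a_in <- unique(as.character(set_a))
  b_in <- unique(as.character(set_b))
  A <- intersect(a_in, universe)
  B <- intersect(b_in, universe)
  N <- length(universe)
  a <- length(intersect(A, B))
  b <- length(A) - a
  cc <- length(B) - a
  d <- N - a - b - cc
  or <- if (a == 0L) 0 else if (b == 0L || cc == 0L) Inf else
    (as.numeric(a) * d) / (as.numeric(b) * cc)
  p <- hyper_two_sided_p(a, length(A), length(B), N)
  structure(list(a = a, b = b, c = cc, d = d, odds_ratio = or, p = p,
                 universe_size = N,
                 degenerate = (b == 0L || cc == 0L) && a > 0L,
                 n_dropped_a = length(a_in) - length(A),
                 n_dropped_b = length(b_in) - length(B)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap: a=%d b=%d c=%d d=%d (N=%d)  OR=%.4g  p=%.4g%s\n",
              x$a, x$b, x$c, x$d, x$universe_size, x$odds_ratio, x$p,
              if (x$degenerate) "  [degenerate table]" else ""))
  invisible(x)
}

#' Split a DE table into female-up and male-up gene sets
#'
#' female_up = genes with FDR strictly below the cutoff and positive
#' logFC; male_up likewise with negative logFC (positive logFC = higher
#' in females).
#'
#' @param de A per-gene DE table with `gene_id`, `logFC`, `adj.P.Val`.
#' @param fdr_cut FDR cutoff (strict `<`).
#' @return List with character vectors `female_up` and `male_up`.
#' @export
split_by_direction <- function(de, fdr_cut = 0.05) {
  stopifnot(all(c("gene_id", "logFC", "adj.P.Val") %in% names(de)))
  sig <- de$adj.P.Val < fdr_cut
  list(female_up = de$gene_id[sig & de$logFC > 0],
       male_up = de$gene_id[sig & de$logFC < 0])
}

## Pseudobulk log-CPM over reference cells (counts genes x cells).
pseudobulk_logcpm <- function(reference_expr) {
  tot <- rowSums(as.matrix(reference_expr))
  log1p(tot / sum(tot) * 1e6) / log(2)
}

#' Expression-matched permutation test of gene-set overlap
#'
#' Tests whether a target set's overlap with a DEG set exceeds what
#' expression-matched random sets achieve.  Genes are stratified into
#' equal-occupancy bins of pseudobulk log-CPM computed from a reference
#' expression matrix (e.g. neuronal single-nucleus counts); each
#' permuted set draws, per stratum, as many non-target genes as the
#' target set has there.  The empirical p places the true odds ratio in
#' the null odds-ratio distribution with the add-one correction
#' `(1 + #\{null OR >= true OR\}) / (n_perm + 1)`, so it is never 0.
#'
#' @param target_set Character vector of target gene identifiers (must
#'   lie in `universe` after intersection).
#' @param deg_set Character vector (e.g. male-up DEGs).
#' @param universe Gene universe for the overlap tables.
#' @param reference_expr genes x cells count matrix used for expression
#'   matching (rownames = gene ids); only universe genes are used.
#' @param n_perm Number of permuted sets.
#' @param n_bins Number of equal-occupancy expression strata.
#' @param seed Integer seed.
#' @return List of class `"matched_null_result"`: `true_or`, `null_or`
#'   (length `n_perm`), `empirical_p`, `true_result` (the
#'   `"overlap_result"`), `matching` (mean log-CPM of target and of
#'   each permuted set).
#' @export
matched_permutation_test <- function(target_set, deg_set, universe,
                                     reference_expr, n_perm = 1000,
                                     n_bins = 25, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", lower = 1L)
  n_bins <- check_count(n_bins, "n_bins", lower = 1L)
  universe <- unique(as.character(universe))
  lcpm_all <- pseudobulk_logcpm(reference_expr)
  if (is.null(names(lcpm_all))) stopf("reference_expr needs gene rownames")
  universe <- intersect(universe, names(lcpm_all))
  target <- intersect(unique(as.character(target_set)), universe)
  if (length(target) == 0L) stopf("no target genes in the universe")
  deg <- intersect(unique(as.character(deg_set)), universe)
  lcpm <- lcpm_all[universe]

  ## equal-occupancy strata of the expression distribution
  br <- unique(quantile(lcpm, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE))
  bin <- cut(lcpm, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- universe
  target_bins <- table(factor(bin[target], levels = seq_along(br[-1])))

  pool_by_bin <- split(setdiff(universe, target),
                       bin[setdiff(universe, target)])
  need <- target_bins[target_bins > 0]
  for (b in names(need)) {
    avail <- length(pool_by_bin[[b]])
    if (is.null(pool_by_bin[[b]]) || avail < need[[b]]) {
      stopf("stratum %s has %d eligible genes but %d are needed; use fewer bins",
            b, avail, need[[b]])
    }
  }

  true_res <- fisher_overlap(target, deg, universe)
  set.seed(check_count(seed, "seed"))
  deg_flag <- universe %in% deg
  names(deg_flag) <- universe
  N <- length(universe)
  n_deg <- sum(deg_flag)
  size <- length(target)
  null_or <- numeric(n_perm)
  mean_lcpm <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    draw <- unlist(lapply(names(need), function(b) {
      sample(pool_by_bin[[b]], need[[b]])
    }), use.names = FALSE)
    a <- sum(deg_flag[draw])
    b2 <- size - a
    c2 <- n_deg - a
    d2 <- N - size - c2
    null_or[j] <- if (a == 0L) 0 else if (b2 == 0L || c2 == 0L) Inf else
      (as.numeric(a) * d2) / (as.numeric(b2) * c2)
    mean_lcpm[j] <- mean(lcpm[draw])
  }
  structure(list(
    true_or = true_res$odds_ratio,
    null_or = null_or,
    empirical_p = (1 + sum(null_or >= true_res$odds_ratio)) / (n_perm + 1),
    true_result = true_res,
    matching = list(target_mean_logcpm = mean(lcpm[target]),
                    null_mean_logcpm = mean_lcpm)),
    class = "matched_null_result")
}

#' @export
print.matched_null_result <- function(x, ...) {
  cat(sprintf("Expression-matched permutation test (%d permutations)\n",
              length(x$null_or)))
  cat(sprintf("  true OR %.3f vs null mean OR %.3f; empirical p = %.4g\n",
              x$true_or, mean(x$null_or[is.finite(x$null_or)]),
              x$empirical_p))
  invisible(x)
}

#' Correlate sex-DE log fold changes with an external logFC table
#'
#' Pearson correlation and least-squares slope of the external logFCs
#' on the sex-DE logFCs over the gene intersection.
#'
#' @param de Per-gene DE table (`gene_id`, `logFC`, optionally
#'   `chromosome`).
#' @param external_lfc Named numeric vector of external (e.g.
#'   case-control) log fold changes.
#' @param exclude_allosomes Drop chrX/chrY genes before correlating.
#' @return List: `r`, `slope`, `n`, `genes`.
#' @export
lfc_correlation <- function(de, external_lfc, exclude_allosomes = FALSE) {
  stopifnot(!is.null(names(external_lfc)))
  tab <- de
  if (exclude_allosomes && !is.null(tab$chromosome)) {
    tab <- tab[!(tab$chromosome %in% c("chrX", "chrY")), , drop = FALSE]
  }
  genes <- intersect(tab$gene_id, names(external_lfc))
  if (length(genes) < 3L) stopf("fewer than 3 shared genes")
  x <- tab$logFC[match(genes, tab$gene_id)]
  y <- external_lfc[genes]
  list(r = cor(x, y), slope = sum((x - mean(x)) * (y - mean(y))) /
         sum((x - mean(x))^2), n = length(genes), genes = genes)
}
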