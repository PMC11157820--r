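## Shared fixtures, generated in code.

## Small two-region bulk dataset with strong, region-shared effects.
small_bulk <- function(seed = 1, n_genes = 800, n_donors = 24,
                       de_fraction = 0.1, effect_mean = 0.8,
                       regions = c("Cortex", "Cerebellum"), ...) {
  generate_bulk_dataset(sim_config(
    n_donors = n_donors, regions = regions, region_sampling_prob = 1,
    n_genes = n_genes, male_fraction = 0.6,
    de_fraction_autosomal = de_fraction,
    de_effect_log2_mean = effect_mean, de_effect_log2_sd = 0.2,
    seed = seed, ...))
}

## A per-gene DE-like table over arbitrary ids.
fake_de_table <- function(gene_id, logFC, p, chromosome = "chr1") {
  data.frame(gene_id = gene_id, logFC = logFC, P.Value = p,
             adj.P.Val = p.adjust(p, "BH"), chromosome = chromosome,
             stringsAsFactors = FALSE)
}

## Single-nucleus fixture: a random Z-weighted gene set plus an optional
## additive program planted on the set genes in a fraction of the Astro
## cells.
make_score_fixture <- function(seed = 1, frac = 1, n_set = 80) {
  sc <- generate_snrna_dataset(sc_config(n_cells = 900, n_genes = 600,
                                         seed = seed))
  set.seed(seed)
  G <- nrow(sc$counts)
  de <- data.frame(gene_id = rownames(sc$counts), logFC = abs(rnorm(G)),
                   P.Value = runif(G), chromosome = "chr1",
                   stringsAsFactors = FALSE)
  gs <- build_weighted_geneset(de, "female_up", top_n = n_set)
  cnt <- sc$counts
  if (frac > 0) {
    on <- which(sc$truth$cell_type == "Astro")
    on <- on[seq_len(round(length(on) * frac))]
    cnt[gs$genes, on] <- cnt[gs$genes, on] +
      matrix(rpois(length(gs$genes) * length(on), 3), length(gs$genes))
    attr(cnt, "program_cells") <- on
  }
  list(sc = sc, gs = gs, cnt = cnt)
}

## Independent brute-force evaluation of the SNR equations: explicit
## loops over samples, no matrix shortcuts.
snr_brute_force <- function(X, Y) {
  F_ <- ncol(X); M_ <- ncol(Y)
  xbar <- apply(X, 1, mean)
  ybar <- apply(Y, 1, mean)
  num <- sqrt(sum((xbar - ybar)^2))
  s2x <- 0
  for (i in seq_len(F_)) s2x <- s2x + sum((X[, i] - xbar)^2)
  s2x <- s2x / (F_ - 1)
  s2y <- 0
  for (i in seq_len(M_)) s2y <- s2y + sum((Y[, i] - ybar)^2)
  s2y <- s2y / (M_ - 1)
  num / sqrt(s2x / F_ + s2y / M_)
}

## Independent two-sided hypergeometric tail from binomial coefficients.
hyper_p_oracle <- function(a, size_a, size_b, N) {
  lo <- max(0, size_a + size_b - N)
  hi <- min(size_a, size_b)
  k <- lo:hi
  probs <- choose(size_a, k) * choose(N - size_a, size_b - k) /
    choose(N, size_b)
  sum(probs[probs <= probs[a - lo + 1] * (1 + 1e-7)])
}
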