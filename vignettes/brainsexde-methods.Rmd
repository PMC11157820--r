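---
title: "Methods: sex-differential expression across brain regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-differential expression across brain regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(brainsexde)
```

This vignette is the package's own account of its statistical
machinery: the models and procedures, the assumptions behind them, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices made where the methodology was genuinely open.

## The analysis problem

Postmortem brain cohorts sample up to eleven brain regions repeatedly
from the same donors.  Roughly 73% of donors are male.  Sex effects on
autosomes are plentiful but tiny (linear fold changes around 1.16),
while allosomal effects are structural: chrY genes are expressed only
in males, a minority of chrX genes escape X inactivation and run
higher in females, and pseudoautosomal (PAR) genes can be
male-shifted.  Technical noise is large and donor-correlated.  The
pipeline therefore runs in stages: filtering and normalisation, a
transcriptome-wide signal check, gene-level modelling, cross-study
confirmation, and integration with disease gene sets and
single-nucleus data.

## Filtering and normalisation

A gene is retained when its raw CPM exceeds `cpm_cutoff` (default 10)
in at least `ceiling(group_fraction * min(group size))` samples.  The
ceiling is deliberate: 70% of a smallest group of 27 is 18.9, and the
threshold used is 19 samples.  The comparison is a strict `>`
(configurable), and filtering uses raw, pre-scaling CPM because it
precedes normalisation in the workflow.

Library scaling is the trimmed mean of M-values: gene-wise log-ratios
against a reference sample (the one whose upper-quartile count
fraction is nearest the cross-sample mean), doubly trimmed — 30% on
the log-ratio scale, 5% on average abundance — and averaged with
delta-method inverse-variance weights, then rescaled to geometric
mean 1.  `tmm_factors()` delegates the computation to edgeR, whose
defaults are exactly this description; the test suite checks the
factors against a from-scratch evaluation of the trimmed-mean
definition.  One numerical caveat found during development: because
the delta-method weights are not scale-free, TMM factors are only
approximately (to about 1e-2, not machine precision) invariant to
rescaling one sample's depth; the pure two-sample depth-change case is
exact.

Log-CPM uses `log2((count + 0.5) / (effective library size + 1) *
1e6)`; both the prior count and the `+1` offset are configurable.

## The signal-to-noise statistic

`compute_snr()` is the ratio of the Euclidean distance between
gene-wise sex means to the pooled standard error of the two groups,
computed over all genes at once.  It deliberately ignores donor
structure (a documented limitation shared with the bulk design: the
statistic asks about raw separability, not inference).  Since SNR
grows with sample size and the sexes are imbalanced, both the "true"
and the "null" distributions are built from equal-size subsamples:
`n = floor(rate * min(F, M))` per sex (rate defaults to 0.90; floor is
the conservative rounding and the worked example — 90 of 100 — cannot
distinguish floor from round), 10⁴ iterations, sampling without
replacement within an iteration and independently across iterations.
Null iterations draw 2n samples regardless of sex and split them into
two arbitrary pseudo-sex groups.

The empirical P is printed as `(SNR_null > SNR_true)/n_iterations`.
Two readings exist; the default is the paired per-iteration fraction
mean(null_i > true_i) — the only reading in which both operands are
per-iteration quantities — and `comparison = "vs_true_mean"` provides
the alternative (fraction of null draws above the true mean).  The
distributions are additionally compared by a two-sided Wilcoxon
rank-sum test.  If both groups are constant the statistic is undefined
and the function errors rather than returning infinity.

## Differential expression

The model is a single group-means fit of logCPM on `~ 0 + SEX_REGION`
plus surrogate covariates, with donor as a random effect.  The pieces:

- **Surrogate covariates** (`estimate_surrogate_covariates()`):
  residualise on the full model, take leading right singular vectors
  of the residual matrix, and keep components whose singular values
  exceed the permutation null (each gene's residuals permuted
  independently; 20 permutations).  The retention rule is the strict
  max rule (`quantile_cut = 1`): with only 20 permutations the 95th
  percentile is noisy and admits ~5% spurious components per seed,
  which the max rule reduces to ~1/21.  Analyses that pre-specify a
  component count can pass `n_sv` directly; how many components an
  iterative surrogate-variable analysis would have chosen is not
  reconstructable from first principles, so the count is exposed as
  configuration.
- **Precision weights** (`voom_transform()`): the standard
  mean-variance trend (lowess span 0.5) turned into observation
  weights, multiplied by per-sample quality weights from sample-wise
  residual dispersion.  Quality weights are clamped to [0.1, 10] —
  an unbounded weight lets a single degenerate sample dominate a
  gene's fit — and renormalised to geometric mean 1.
- **Donor blocking** (`estimate_duplicate_correlation()`): per-gene
  within-donor residual correlations combined through
  tanh(trimmed mean(atanh)) into one consensus value, used in a
  gene-wise GLS fit under block-equicorrelated covariance.  This is a
  consensus-correlation approximation, not per-gene REML mixed models;
  at the scale of these designs it is the standard, well-tested
  compromise.
- **Contrasts**: per-region Female − Male columns and an omnibus
  column equal to their elementwise mean (entries ±1/n_regions),
  giving every region equal weight regardless of its sample count —
  the omnibus is "the average sex effect across regions", not "the
  sex effect in the pooled data".  Positive logFC = higher in
  females, always.
- **Moderation**: residual variances are shrunk toward a scaled-F
  prior fitted by moment-matching on the log scale; moderated t uses
  the augmented degrees of freedom; BH is applied within each contrast
  separately (the single-model design is what makes the contrasts
  comparable, so no cross-contrast correction is layered on top).

## Two-study meta-analysis

Genes are intersected by identifier and kept only when the logFC sign
agrees across studies; zero logFC has no sign and is dropped (counts
logged on the returned object).  P-value combination is either
Fisher's `-2 Σ ln p` against chi-square with 2k df, or the adaptively
weighted variant: for two studies the three non-zero binary weight
vectors are enumerated, the smallest subset-Fisher p is the statistic,
and its null distribution is calibrated with one shared Monte-Carlo
table of the same minimum under independent uniforms (default 10⁶
draws, seeded).  Ties between weight vectors go to the all-ones
vector.  Inputs are the studies' two-sided p-values as-is — the
direction filter has already handled one-sidedness.  The combined
p-values are BH-adjusted.

## Gene-set overlap and the expression-matched null

`fisher_overlap()` always intersects both sets with the analysis
universe first, then tests the 2×2 table.  The odds ratio is the
sample odds ratio ad/bc with the convention OR = 0 when the overlap is
empty; b = 0 or c = 0 yields an infinite OR flagged as degenerate
rather than an error.  The two-sided p comes directly from the
hypergeometric pmf (ties counted at a 1 + 1e-7 relative tolerance,
matching the conventional implementation); the suite verifies it
against both an independent binomial-coefficient enumeration of every
table with universe ≤ 40 and `stats::fisher.test`.

The expression-matched permutation test guards against a specific
confound: a disease gene set may overlap male-up DEGs simply because
both are neuronal and highly expressed.  Genes are stratified into
equal-occupancy pseudobulk log-CPM bins (default 25) computed from a
reference expression matrix restricted to the relevant cell types;
each of `n_perm` (default 1000) permuted sets draws, per stratum, as
many non-target genes as the target holds there.  The empirical p is
`(1 + #{null OR ≥ true OR}) / (n_perm + 1)` — the add-one correction
keeps it strictly positive, and ties count against significance.
"Similar expression" admits many matching schemes; equal-occupancy
strata with within-stratum uniform sampling is the simplest one
consistent with the goal, and the bin count is configurable (with one
bin the test degenerates, verifiably, to unmatched random sets).

## Per-cell weighted gene-set scoring

This stage is a simplified re-implementation of the per-cell
disease-relevance-scoring idea, not a port of any particular tool.
Gene sets are the top `top_n` (default 1000) autosomal genes of one
direction, weighted by the Z-transform of their DE p-values.  A cell's
raw score is the weighted mean of its log1p-CPM expression over the
set; `n_ctrl` (default 1500) control sets replace each set gene with a
random gene from the same joint (mean, variance) equal-occupancy bin
(default 10×10), giving per-cell empirical p-values and a normalised
score (raw minus control mean over control SD).  Cells with under 250
detected genes and genes seen in under 1% of cells are dropped first.

Group-level tests needed two design decisions that the per-cell
machinery does not dictate:

- the enrichment statistic is the *standardised deviation* of the
  group mean from the all-cell mean (divided by the score set's own
  cross-cell SD), and
- each Monte-Carlo null draw pairs a control gene set with a freshly
  resampled cell group of the same size.

Both were forced by calibration: a gene set with any global
association has cross-cell score fluctuations larger than its control
sets', so the naive "group mean vs control group means" comparison
flags every group — including randomly relabelled ones.  With
centring, standardisation and membership resampling, label
permutation destroys enrichment (verified over seeds) while planted
programs remain detected.  Heterogeneity is the within-group variance
of normalised scores against the same null; a homogeneous planted
shift triggers enrichment only, a program confined to half of a
type's cells triggers both.  Group p-values are Bonferroni-corrected
across groups.

## The synthetic-data generator

`generate_bulk_dataset()` emulates the structure the analysis
assumes: donors × regions sampling with per-region inclusion
probability, 72.9% male donors, eleven brain-region names, gene
baselines spanning ~6 log2 units, negative-binomial counts with
per-gene dispersions uniform on (0.05, 0.5), latent batch factors,
lognormal target library sizes, and truth tables for every injected
effect.  Autosomal effects have |log2FC| ~ N(0.21, 0.10), calibrated
so the mean absolute linear fold change of injected autosomal effects
is ≈1.158; chrY genes are structurally zero in females (true logFC
−∞); 15% of chrX genes carry a female-up escape effect near 1 log2
unit; PAR genes are male-shifted by 0.3.

One deviation from the obvious parameterisation is deliberate: the
donor random effect is a per-donor, *per-gene* intercept shared across
that donor's repeated samples.  A per-donor scalar shared by all genes
is just a library-depth shift — CPM normalisation cancels it exactly,
leaving nothing for donor blocking to detect — so the per-gene form
is the simplest structure under which `duplicateCorrelation`-style
blocking is testable (donor_sd 0.3 yields consensus correlations
around 0.15).

What the generator does **not** emulate: realistic genome coordinates
or transcript structure, region-specific effect-size distributions
(exposed as free parameters instead, since no reliable external values
exist for them), GC/length biases, ambient contamination or doublets
in the single-nucleus generator, and donor covariates such as age.
Passing tests on this generator therefore demonstrate that the
statistical machinery is correct under its stated model, not that the
model captures every failure mode of real tissue data.

`generate_snrna_dataset()` produces cell types in exact
largest-remainder proportions with marker programs (default 8-fold)
and optional within-type state programs; `generate_gene_sets()` draws
sets with controlled size, chrX composition and expression-quantile
bias.

## Numerical choices collected

- Sample-threshold rounding: ceiling.  SNR subsample rounding: floor.
- CPM filter inequality: strict `>`.
- Empirical p-values: add-one correction, ties against significance;
  the SNR empirical P is the exception because its printed definition
  has no correction (it can be exactly 0).
- Parallel-analysis retention: strict max over 20 permutations.
- AW-Fisher ties: all-ones weight vector.
- Quality-weight clamp: [0.1, 10], geometric mean 1.
- Consensus correlation clamped strictly inside (−1, 1).
- Zero denominators error early (constant SNR groups, empty universes,
  empty strata) with messages naming the offending quantity.

## Problem sizes

The test suite and the acceptance script run on deliberately modest
simulations — hundreds to a few thousand genes, tens of donors, 10²–10⁴
permutation iterations depending on the check — chosen so the whole
validation cycle completes in minutes while every statistical claim
(calibration under the null, power under planted effects, oracle
equivalence at 1e-10–1e-12) is still exercised at meaningful
resolution.  All stages scale to full-cohort sizes; the SNR and
control-set computations are the ones worth watching, and both are
vectorised.

## Known limitations

- The consensus-correlation GLS is an approximation to per-gene mixed
  models; genes whose true intra-donor correlation departs far from
  the consensus are mis-weighted.
- The SNR statistic ignores donor structure by design.
- AW-Fisher calibration is Monte-Carlo, so combined p-values below
  ~1/mc_reps are truncated; raise `mc_reps` when tail precision
  matters.
- Expression matching controls one confound (expression level); other
  gene covariates (length, GC, cell-type specificity breadth) are not
  matched.
- The group heterogeneity test reacts to any within-group variance
  inflation, including technical structure uncorrelated with the gene
  set.
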