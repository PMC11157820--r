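Package: brainsexde
Title: Sex-Differential Gene Expression Analysis Across Brain Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting sex-differential gene expression in
    multi-region bulk RNA-seq designs with repeated sampling of donors, and
    for relating the resulting gene lists to disease gene sets.  Provides
    low-expression filtering and TMM/logCPM normalisation, a subsampled
    transcriptome-wide signal-to-noise-ratio permutation framework, voom-style
    differential expression with surrogate covariates, donor blocking,
    per-region and omnibus sex contrasts and empirical-Bayes moderation,
    direction-concordant two-study meta-analysis (Fisher and adaptively
    weighted Fisher), direction-split gene-set overlap tests with an
    expression-matched permutation null, weighted per-cell gene-set scoring
    for single-nucleus data, and a synthetic-data generator with ground truth
    so every stage is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    limma,
    edgeR,
    Matrix,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
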