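## Synthetic bulk and single-nucleus data with known ground truth.
##
## The generator emulates the structure of large multi-region postmortem
## brain RNA-seq collections: repeated sampling of donors across regions,
## a ~73%/27% male/female imbalance, strong allosomal sex effects (X
## escape, male-limited chrY expression, male-shifted pseudoautosomal
## genes), weak autosomal sex effects, a shared per-donor intercept,
## latent batch factors, and negative-binomial counts.

GTEX_REGIONS <- c(
  "Amygdala", "AnteriorCingulateCortex", "Caudate", "Cerebellum",
  "Cortex", "Hippocampus", "Hypothalamus", "NucleusAccumbens",
  "Putamen", "SpinalCord", "SubstantiaNigra"
)

#' Simulation configuration for the bulk generator
#'
#' Builds and validates the parameter list consumed by
#' [generate_bulk_dataset()].  Defaults mirror the composition of the
#' multi-region brain cohort the pipeline is designed for: 11 brain
#' regions, a 72.9% male donor fraction, donors contributing roughly
#' two-thirds of regions each, a small allosomal gene complement, and
#' weak autosomal sex effects whose mean absolute linear fold change is
#' approximately 1.158.
#'
#' @param n_donors Number of donors (>= 2).
#' @param male_fraction Probability that a donor is male.
#' @param regions Character vector of region names.
#' @param region_sampling_prob Probability that a given donor contributes a
#'   sample for a given region.
#' @param n_genes Total number of genes (>= 10).
#' @param allosomal_fraction Fraction of genes on sex chromosomes.
#' @param allosome_split Proportions of allosomal genes that are chrX, chrY
#'   and pseudoautosomal (PAR); must sum to 1.
#' @param de_fraction_autosomal Fraction of autosomal genes given a true sex
#'   effect.
#' @param de_effect_log2_mean,de_effect_log2_sd Mean and SD of the absolute
#'   autosomal effect size on the log2 scale (sign is random).  The default
#'   mean of 0.21 makes the mean absolute linear fold change of injected
#'   autosomal effects about 1.158.
#' @param de_region_fraction Probability that a DE gene's effect is present
#'   in any given region (each DE gene affects at least one region).
#' @param x_escape_fraction Fraction of chrX genes with a female-up escape
#'   effect.
#' @param x_effect_log2 Mean female-up log2 effect of escape genes.
#' @param par_effect_log2 Male-up log2 shift applied to PAR genes (0 turns
#'   it off).
#' @param donor_sd SD of the per-donor intercept (log2 scale), shared
#'   across genes.
#' @param n_batch_factors Number of latent batch factors.
#' @param batch_sd SD of the batch contribution (log2 scale).
#' @param nb_dispersion_range Range of the per-gene negative-binomial
#'   dispersion (uniform draw); lower bound must be > 0.
#' @param library_size_mean,library_size_cv Mean and coefficient of
#'   variation of target library sizes (lognormal).
#' @param seed Integer seed; identical configs give bit-identical output.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_donors = 240,
                       male_fraction = 0.729,
                       regions = GTEX_REGIONS,
                       region_sampling_prob = 0.64,
                       n_genes = 5000,
                       allosomal_fraction = 0.035,
                       allosome_split = c(chrX = 0.92, chrY = 0.04, PAR = 0.04),
                       de_fraction_autosomal = 0.06,
                       de_effect_log2_mean = 0.21,
                       de_effect_log2_sd = 0.10,
                       de_region_fraction = 1,
                       x_escape_fraction = 0.15,
                       x_effect_log2 = 1.0,
                       par_effect_log2 = 0.3,
                       donor_sd = 0.3,
                       n_batch_factors = 2,
                       batch_sd = 0.2,
                       nb_dispersion_range = c(0.05, 0.5),
                       library_size_mean = 1e6,
                       library_size_cv = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_donors = check_count(n_donors, "n_donors", lower = 2L),
    male_fraction = check_proportion(male_fraction, "male_fraction"),
    regions = as.character(regions),
    region_sampling_prob = check_proportion(region_sampling_prob,
                                            "region_sampling_prob"),
    n_genes = check_count(n_genes, "n_genes", lower = 10L),
    allosomal_fraction = check_proportion(allosomal_fraction,
                                          "allosomal_fraction"),
    allosome_split = allosome_split,
    de_fraction_autosomal = check_proportion(de_fraction_autosomal,
                                             "de_fraction_autosomal"),
    de_effect_log2_mean = check_number(de_effect_log2_mean,
                                       "de_effect_log2_mean", lower = 0),
    de_effect_log2_sd = check_number(de_effect_log2_sd,
                                     "de_effect_log2_sd", lower = 0),
    de_region_fraction = check_proportion(de_region_fraction,
                                          "de_region_fraction"),
    x_escape_fraction = check_proportion(x_escape_fraction,
                                         "x_escape_fraction"),
    x_effect_log2 = check_number(x_effect_log2, "x_effect_log2"),
    par_effect_log2 = check_number(par_effect_log2, "par_effect_log2"),
    donor_sd = check_number(donor_sd, "donor_sd", lower = 0),
    n_batch_factors = check_count(n_batch_factors, "n_batch_factors"),
    batch_sd = check_number(batch_sd, "batch_sd", lower = 0),
    nb_dispersion_range = nb_dispersion_range,
    library_size_mean = check_number(library_size_mean, "library_size_mean",
                                     lower = 0, strict_lower = TRUE),
    library_size_cv = check_number(library_size_cv, "library_size_cv",
                                   lower = 0),
    seed = check_count(seed, "seed")
  )
  if (length(cfg$regions) < 1L || anyDuplicated(cfg$regions)) {
    stopf("'regions' must be a non-empty vector of unique names")
  }
  if (length(cfg$allosome_split) != 3L ||
      abs(sum(cfg$allosome_split) - 1) > 1e-8 ||
      any(cfg$allosome_split < 0)) {
    stopf("'allosome_split' must be 3 non-negative proportions summing to 1")
  }
  if (length(cfg$nb_dispersion_range) != 2L ||
      cfg$nb_dispersion_range[1] <= 0 ||
      diff(cfg$nb_dispersion_range) < 0) {
    stopf("'nb_dispersion_range' must be an increasing pair with lower bound > 0")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic multi-region bulk RNA-seq dataset
#'
#' Draws negative-binomial counts around a log-linear mean combining a
#' per-gene baseline abundance, a sex effect (region-specific for DE
#' genes; female-minus-male sign convention), a per-donor random
#' intercept, and latent batch loadings.  chrY genes are structurally
#' zero in female samples; a configurable fraction of chrX genes carry a
#' female-up escape effect; PAR genes carry a male-up shift.
#'
#' @param config A [sim_config()] object.
#' @return A list with
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, with dimnames.}
#'     \item{samples}{data.frame: sample_id, donor, sex
#'       ("Female"/"Male"), region.}
#'     \item{genes}{data.frame: gene_id, chromosome, par (logical).}
#'     \item{truth}{list: `lfc` (gene x region matrix of true log2
#'       fold changes, female minus male; `-Inf` for chrY), `de`
#'       (logical gene x region matrix), `donor_effect`,
#'       `batch_scores`, `batch_loadings`, `target_lib_size`.}
#'   }
#' @export
generate_bulk_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  G <- config$n_genes
  regions <- config$regions
  R <- length(regions)

  ## gene annotation
  n_allo <- round(G * config$allosomal_fraction)
  n_x <- round(n_allo * config$allosome_split[[1]])
  n_y <- round(n_allo * config$allosome_split[[2]])
  n_par <- n_allo - n_x - n_y
  n_auto <- G - n_allo
  chrom <- c(sample(paste0("chr", 1:22), n_auto, replace = TRUE),
             rep("chrX", n_x), rep("chrY", n_y), rep("chrX", n_par))
  par_flag <- c(rep(FALSE, n_auto + n_x + n_y), rep(TRUE, n_par))
  gene_id <- sprintf("ENSG%011d", seq_len(G))
  genes <- data.frame(gene_id = gene_id, chromosome = chrom, par = par_flag,
                      stringsAsFactors = FALSE)
  is_auto <- !(chrom %in% c("chrX", "chrY"))
  is_y <- chrom == "chrY" & !par_flag
  is_x <- chrom == "chrX" & !par_flag

  ## samples: donors x regions, each region kept with sampling prob
  donor_id <- sprintf("D%04d", seq_len(config$n_donors))
  donor_sex <- ifelse(runif(config$n_donors) < config$male_fraction,
                      "Male", "Female")
  ## guarantee both sexes so downstream contrasts exist
  if (length(unique(donor_sex)) == 1L) {
    donor_sex[1] <- setdiff(c("Male", "Female"), donor_sex[1])
  }
  keep <- matrix(runif(config$n_donors * R) < config$region_sampling_prob,
                 config$n_donors, R)
  samples <- data.frame(
    sample_id = character(0), donor = character(0),
    sex = character(0), region = character(0), stringsAsFactors = FALSE)
  idx <- which(keep, arr.ind = TRUE)
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(nrow(idx))),
    donor = donor_id[idx[, 1]],
    sex = donor_sex[idx[, 1]],
    region = regions[idx[, 2]],
    stringsAsFactors = FALSE)
  S <- nrow(samples)
  if (S < 4L) stopf("configuration error: 'region_sampling_prob' too low, only %d samples generated", S)

  ## true effects (female minus male, log2)
  lfc <- matrix(0, G, R, dimnames = list(gene_id, regions))
  de <- matrix(FALSE, G, R, dimnames = list(gene_id, regions))
  auto_idx <- which(is_auto)
  n_de <- round(length(auto_idx) * config$de_fraction_autosomal)
  de_genes <- if (n_de > 0) sample(auto_idx, n_de) else integer(0)
  if (n_de > 0) {
    mag <- abs(rnorm(n_de, config$de_effect_log2_mean,
                     config$de_effect_log2_sd))
    eff <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    for (i in seq_len(n_de)) {
      in_region <- runif(R) < config$de_region_fraction
      if (!any(in_region)) in_region[sample.int(R, 1)] <- TRUE
      lfc[de_genes[i], in_region] <- eff[i]
      de[de_genes[i], in_region] <- TRUE
    }
  }
  x_idx <- which(is_x)
  n_esc <- round(length(x_idx) * config$x_escape_fraction)
  if (n_esc > 0) {
    esc <- sample(x_idx, n_esc)
    lfc[esc, ] <- abs(rnorm(n_esc, config$x_effect_log2, 0.3))
    de[esc, ] <- TRUE
  }
  if (n_par > 0 && config$par_effect_log2 != 0) {
    lfc[which(par_flag), ] <- -config$par_effect_log2
    de[which(par_flag), ] <- TRUE
  }
  if (sum(is_y) > 0) {
    lfc[which(is_y), ] <- -Inf  # male-limited expression
    de[which(is_y), ] <- TRUE
  }

  ## nuisance structure.  The donor effect is a per-donor, per-gene
  ## intercept shared across that donor's repeated samples: a scalar
  ## intercept common to all genes would be a pure depth shift that CPM
  ## normalisation cancels, leaving nothing for donor blocking to find.
  donor_eff <- matrix(rnorm(G * config$n_donors, 0, config$donor_sd),
                      G, config$n_donors, dimnames = list(gene_id, donor_id))
  K <- config$n_batch_factors
  batch_load <- matrix(rnorm(G * max(K, 1L)), G, max(K, 1L))
  batch_scores <- matrix(rnorm(S * max(K, 1L)), S, max(K, 1L))
  batch_term <- if (K > 0) {
    config$batch_sd / sqrt(K) *
      batch_load[, seq_len(K), drop = FALSE] %*%
      t(batch_scores[, seq_len(K), drop = FALSE])
  } else matrix(0, G, S)

  ## baseline relative abundance (log2 CPM-ish spread)
  base_log2 <- rnorm(G, 4, 2)
  sex_sign <- ifelse(samples$sex == "Female", 0.5, -0.5)
  region_col <- match(samples$region, regions)
  target_lib <- exp(rnorm(S, log(config$library_size_mean),
                          sqrt(log(1 + config$library_size_cv^2))))

  eta <- matrix(base_log2, G, S) + batch_term +
    donor_eff[, samples$donor, drop = FALSE]
  lfc_sample <- lfc[, region_col, drop = FALSE]
  lfc_sample[!is.finite(lfc_sample)] <- 0
  eta <- eta + sweep(lfc_sample, 2L, sex_sign, "*")
  rel <- 2^eta
  ## chrY expressed only in males
  rel[is_y, samples$sex == "Female"] <- 0
  rel <- sweep(rel, 2L, colSums(rel), "/")
  mu <- sweep(rel, 2L, target_lib, "*")

  disp <- runif(G, config$nb_dispersion_range[1], config$nb_dispersion_range[2])
  counts <- matrix(rnbinom(G * S, mu = mu, size = rep(1 / disp, S)), G, S,
                   dimnames = list(gene_id, samples$sample_id))
  storage.mode(counts) <- "integer"

  list(counts = counts, samples = samples, genes = genes,
       truth = list(lfc = lfc, de = de, donor_effect = donor_eff,
                    batch_scores = batch_scores[, seq_len(K), drop = FALSE],
                    batch_loadings = batch_load[, seq_len(K), drop = FALSE],
                    dispersion = disp, target_lib_size = target_lib))
}

#' Single-nucleus simulation configuration
#'
#' @param n_cells Total number of cells (> 0).
#' @param n_genes Number of genes.
#' @param cell_type_props Named numeric vector of cell-type proportions
#'   (>= 2 types; must sum to 1).  Cell counts are assigned by largest
#'   remainder so they match the proportions within rounding.
#' @param n_states_per_type Integer, number of within-type states (>= 1);
#'   states split each type's cells evenly.
#' @param state_effect_log2 log2 up-shift of the state program genes in
#'   cells of state 2 and above (0 disables the program).
#' @param markers_per_type Marker genes per cell type.
#' @param marker_fold_change Linear fold change of markers in their own
#'   type relative to other types.
#' @param program_genes_per_type Genes in each type's state program.
#' @param n_donors Donors cells are assigned to (half male, half female).
#' @param library_size_mean Mean per-cell depth (lognormal, cv 0.3).
#' @param seed Integer seed.
#' @return Validated list of class `"sc_config"`.
#' @export
sc_config <- function(n_cells = 2000,
                      n_genes = 1000,
                      cell_type_props = c(Neuron = 0.5, Astro = 0.25,
                                          Oligo = 0.25),
                      n_states_per_type = 1,
                      state_effect_log2 = 0,
                      markers_per_type = 25,
                      marker_fold_change = 8,
                      program_genes_per_type = 25,
                      n_donors = 8,
                      library_size_mean = 5000,
                      seed = 1L) {
  cfg <- list(
    n_cells = check_count(n_cells, "n_cells", lower = 1L),
    n_genes = check_count(n_genes, "n_genes", lower = 10L),
    cell_type_props = cell_type_props,
    n_states_per_type = check_count(n_states_per_type, "n_states_per_type",
                                    lower = 1L),
    state_effect_log2 = check_number(state_effect_log2, "state_effect_log2"),
    markers_per_type = check_count(markers_per_type, "markers_per_type"),
    marker_fold_change = check_number(marker_fold_change,
                                      "marker_fold_change", lower = 1),
    program_genes_per_type = check_count(program_genes_per_type,
                                         "program_genes_per_type"),
    n_donors = check_count(n_donors, "n_donors", lower = 2L),
    library_size_mean = check_number(library_size_mean, "library_size_mean",
                                     lower = 0, strict_lower = TRUE),
    seed = check_count(seed, "seed")
  )
  p <- cfg$cell_type_props
  if (length(p) < 2L || is.null(names(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8) {
    stopf("'cell_type_props' must be >= 2 named non-negative proportions summing to 1")
  }
  structure(cfg, class = "sc_config")
}

## Largest-remainder apportionment of n among proportions p.
apportion <- function(n, p) {
  raw <- n * p
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  }
  as.integer(k)
}

#' Generate a synthetic single-nucleus RNA-seq dataset
#'
#' Cells carry type-specific marker programs and, optionally, a
#' within-type state program (an additive log2 shift on a dedicated gene
#' block in a subset of states).  Counts are Poisson around a per-cell
#' depth.  Returned truth labels allow per-cell scoring and group tests
#' to be validated against a known answer.
#'
#' @param config An [sc_config()] object.
#' @return A list with `counts` (genes x cells integer matrix) and
#'   `truth` (data.frame per cell: cell_id, cell_type, state, donor,
#'   sex) plus `gene_info` (data.frame: gene_id, marker_of,
#'   program_of).
#' @export
generate_snrna_dataset <- function(config = sc_config()) {
  if (!inherits(config, "sc_config")) config <- do.call(sc_config, config)
  set.seed(config$seed)
  types <- names(config$cell_type_props)
  n_type <- apportion(config$n_cells, config$cell_type_props)
  cell_type <- rep(types, n_type)
  n <- length(cell_type)
  ## states partition cells within a type
  state <- unlist(lapply(n_type, function(k) {
    rep_len(seq_len(config$n_states_per_type), k)
  }))
  donor <- sprintf("D%02d", rep_len(seq_len(config$n_donors), n))
  sex <- ifelse(as.integer(sub("D", "", donor)) %% 2 == 0, "Female", "Male")

  G <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(G))
  marker_of <- rep(NA_character_, G)
  program_of <- rep(NA_character_, G)
  pos <- 1L
  for (ty in types) {
    mk <- seq(pos, length.out = config$markers_per_type)
    marker_of[mk] <- ty
    pos <- pos + config$markers_per_type
    pg <- seq(pos, length.out = config$program_genes_per_type)
    program_of[pg] <- ty
    pos <- pos + config$program_genes_per_type
  }
  if (pos > G + 1L) stopf("configuration error: n_genes too small for the requested marker/program blocks")

  base_log2 <- rnorm(G, 2, 1.5)
  eta <- matrix(base_log2, G, n)
  for (ty in types) {
    mk <- which(marker_of == ty)
    eta[mk, cell_type != ty] <- eta[mk, cell_type != ty] -
      log2(config$marker_fold_change)
    if (config$state_effect_log2 != 0 && config$n_states_per_type > 1) {
      pg <- which(program_of == ty)
      on <- cell_type == ty & state > 1
      eta[pg, on] <- eta[pg, on] + config$state_effect_log2
    }
  }
  rel <- 2^eta
  rel <- sweep(rel, 2L, colSums(rel), "/")
  depth <- exp(rnorm(n, log(config$library_size_mean),
                     sqrt(log(1 + 0.3^2))))
  counts <- matrix(stats::rpois(G * n, sweep(rel, 2L, depth, "*")), G, n)
  cell_id <- sprintf("C%05d", seq_len(n))
  dimnames(counts) <- list(gene_id, cell_id)
  storage.mode(counts) <- "integer"

  list(counts = counts,
       truth = data.frame(cell_id = cell_id, cell_type = cell_type,
                          state = state, donor = donor, sex = sex,
                          stringsAsFactors = FALSE),
       gene_info = data.frame(gene_id = gene_id, marker_of = marker_of,
                              program_of = program_of,
                              stringsAsFactors = FALSE))
}

#' Generate synthetic gene sets with controlled composition
#'
#' Draws named gene sets honouring a requested size, chromosome
#' composition (number of chrX members), and an optional bias toward an
#' expression quantile band of a reference profile -- the ingredients
#' needed to exercise overlap and expression-matched permutation tests.
#'
#' @param annotations data.frame with columns `gene_id` and `chromosome`.
#' @param expression_reference Named numeric vector of reference log-CPM
#'   per gene (names matching `gene_id`); required when any set requests
#'   an expression-quantile bias.
#' @param set_specs A named list; each element a list with fields
#'   `size` (integer), and optionally `n_chrx` (integer, default 0 means
#'   unconstrained) and `quantile_range` (length-2 numeric in [0,1];
#'   genes drawn only from that band of the reference expression
#'   distribution).
#' @param seed Integer seed.
#' @return Named list of character vectors of gene identifiers.
#' @export
generate_gene_sets <- function(annotations, expression_reference = NULL,
                               set_specs, seed = 1L) {
  stopifnot(is.data.frame(annotations),
            all(c("gene_id", "chromosome") %in% names(annotations)))
  set.seed(check_count(seed, "seed"))
  out <- vector("list", length(set_specs))
  names(out) <- names(set_specs)
  for (nm in names(set_specs)) {
    sp <- set_specs[[nm]]
    size <- check_count(sp$size, "size", lower = 1L)
    pool <- annotations$gene_id
    if (!is.null(sp$quantile_range)) {
      if (is.null(expression_reference)) {
        stopf("set '%s' requests an expression bias but no expression_reference given", nm)
      }
      qr <- quantile(expression_reference, sp$quantile_range, names = FALSE)
      ok <- names(expression_reference)[expression_reference >= qr[1] &
                                          expression_reference <= qr[2]]
      pool <- intersect(pool, ok)
    }
    chrx_pool <- pool[annotations$chromosome[match(pool, annotations$gene_id)]
                      == "chrX"]
    other_pool <- setdiff(pool, chrx_pool)
    n_chrx <- if (is.null(sp$n_chrx)) NA_integer_ else
      check_count(sp$n_chrx, "n_chrx")
    if (is.na(n_chrx)) {
      if (length(pool) < size) {
        stopf("set '%s': requested size %d exceeds %d eligible genes",
              nm, size, length(pool))
      }
      out[[nm]] <- sample(pool, size)
    } else {
      if (length(chrx_pool) < n_chrx || length(other_pool) < size - n_chrx) {
        stopf("set '%s': infeasible composition (need %d chrX of %d eligible, %d others of %d eligible)",
              nm, n_chrx, length(chrx_pool), size - n_chrx,
              length(other_pool))
      }
      out[[nm]] <- c(sample(chrx_pool, n_chrx),
                     sample(other_pool, size - n_chrx))
    }
  }
  out
}
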