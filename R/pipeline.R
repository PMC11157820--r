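## Orchestration: configuration, stage sequencing, output manifest,
## input validation.

#' Demo pipeline configuration
#'
#' A small end-to-end configuration (synthetic data, 2 regions, 2000
#' genes) exercising every stage.  Any field can be overridden via
#' `...` or by editing the returned list; unknown keys are rejected at
#' run time.
#'
#' @param outdir Output directory.
#' @param seed Global seed; per-stage seeds are derived from it by
#'   stage-name hashing so stages are independently reproducible.
#' @param ... Top-level overrides (`stages`, `simulate`, `snr`, `de`,
#'   `meta`, `enrichment`, `cellscore`).
#' @return Configuration list for [run_pipeline()].
#' @export
demo_pipeline_config <- function(outdir = tempfile("brainsexde-run-"),
                                 seed = 1L, ...) {
  cfg <- list(
    outdir = outdir,
    seed = seed,
    stages = list(simulate = TRUE, preprocess = TRUE, snr = TRUE,
                  de = TRUE, meta = TRUE, enrichment = TRUE,
                  cellscore = TRUE),
    simulate = list(n_donors = 40, regions = c("Cortex", "Cerebellum"),
                    region_sampling_prob = 1, n_genes = 2000,
                    male_fraction = 0.6, de_fraction_autosomal = 0.08,
                    de_effect_log2_mean = 0.8, de_effect_log2_sd = 0.2),
    preprocess = list(cpm_cutoff = 1, group_fraction = 0.70),
    snr = list(n_iterations = 500, subsample_rate = 0.90),
    de = list(n_sv = 2, block_donor = TRUE),
    meta = list(contrast = "Cortex", mc_reps = 1e5),
    enrichment = list(contrast = "Omnibus", set_size = 100, n_perm = 200,
                      n_bins = 10),
    cellscore = list(top_n = 200, n_ctrl = 200, n_cells = 1000,
                     n_genes = 600)
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

pipeline_stage_names <- c("simulate", "preprocess", "snr", "de", "meta",
                          "enrichment", "cellscore")

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order -- simulate ->
#' preprocess -> SNR -> DE -> meta -> enrichment -> cell scoring --
#' writing each stage's tables under `config$outdir` and recording
#' every written file with its MD5 content hash in the returned
#' manifest.  Re-running with an identical config reproduces identical
#' hashes.
#'
#' @param config Configuration list (see [demo_pipeline_config()]), or
#'   the path to a YAML file holding one.
#' @return List: `manifest` (data.frame stage/file/md5), `results`
#'   (in-memory stage outputs), `config`.
#' @export
run_pipeline <- function(config = demo_pipeline_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  allowed <- c("outdir", "seed", "stages", pipeline_stage_names,
               "preprocess")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) {
    stopf("unknown configuration keys: %s", paste(unknown, collapse = ", "))
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- check_count(config$seed %||% 1L, "seed")
  on_stage <- function(s) isTRUE(config$stages[[s]])
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), stringsAsFactors = FALSE)
  emit <- function(stage, path) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE))
  }
  results <- list()
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stopf("pipeline halted in stage '%s': %s", name, conditionMessage(e))
    })
  }

  ## --- simulate -----------------------------------------------------
  dat <- NULL
  if (on_stage("simulate")) {
    run_stage("simulate", function() {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- derive_seed(seed, "simulate")
      dat <<- generate_bulk_dataset(do.call(sim_config, sim_args))
      write_counts_tsv(dat$counts, file.path(outdir, "counts.tsv"))
      write_tsv(dat$samples, file.path(outdir, "samples.tsv"))
      write_tsv(dat$genes, file.path(outdir, "genes.tsv"))
      truth_lfc <- data.frame(gene_id = rownames(dat$truth$lfc),
                              dat$truth$lfc, check.names = FALSE)
      write_tsv(truth_lfc, file.path(outdir, "truth_lfc.tsv"))
      for (f in c("counts.tsv", "samples.tsv", "genes.tsv",
                  "truth_lfc.tsv")) emit("simulate", file.path(outdir, f))
      results$simulate <<- dat
    })
  }
  if (is.null(dat)) stopf("downstream stages need the simulate stage (or preloaded data)")

  ## --- preprocess ---------------------------------------------------
  counts <- dat$counts; samples <- dat$samples; genes <- dat$genes
  norm <- NULL
  if (on_stage("preprocess")) {
    run_stage("preprocess", function() {
      pp <- config$preprocess %||% list()
      gsz <- table(paste(samples$sex, samples$region, sep = "_"))
      mask <- filter_low_expression(counts, as.integer(gsz),
                                    cpm_cutoff = pp$cpm_cutoff %||% 10,
                                    group_fraction = pp$group_fraction %||% 0.70)
      counts <<- counts[mask, , drop = FALSE]
      genes <<- genes[mask, , drop = FALSE]
      norm <<- tmm_factors(counts)
      write_tsv(data.frame(sample_id = samples$sample_id,
                           norm_factor = norm$norm_factors,
                           lib_size = norm$lib_size,
                           effective_lib_size = norm$effective_lib_size),
                file.path(outdir, "norm_factors.tsv"))
      emit("preprocess", file.path(outdir, "norm_factors.tsv"))
      results$preprocess <<- list(mask = mask, norm = norm,
                                  min_samples = attr(mask, "min_samples"))
    })
  }
  if (is.null(norm)) norm <- tmm_factors(counts)
  logcpm <- log_cpm(counts, norm$effective_lib_size)

  ## --- snr ----------------------------------------------------------
  if (on_stage("snr")) {
    run_stage("snr", function() {
      sp <- config$snr %||% list()
      cfgs <- snr_config(n_iterations = sp$n_iterations %||% 10000,
                         subsample_rate = sp$subsample_rate %||% 0.90,
                         seed = derive_seed(seed, "snr"))
      res <- lapply(unique(samples$region), function(r) {
        run_snr_analysis(logcpm, samples, r, cfgs)
      })
      tab <- snr_table(res)
      write_tsv(tab, file.path(outdir, "snr.tsv"))
      emit("snr", file.path(outdir, "snr.tsv"))
      results$snr <<- tab
    })
  }

  ## --- de -----------------------------------------------------------
  de_res <- NULL
  if (on_stage("de")) {
    run_stage("de", function() {
      dp <- config$de %||% list()
      de_res <<- run_de_analysis(counts, samples, genes,
                                 n_sv = dp$n_sv,
                                 block_donor = dp$block_donor %||% TRUE,
                                 seed = derive_seed(seed, "de"))
      for (cn in unique(de_res$de$contrast)) {
        f <- file.path(outdir, paste0("de_", cn, ".tsv"))
        write_tsv(de_res$de[de_res$de$contrast == cn, ], f)
        emit("de", f)
      }
      results$de <<- de_res
    })
  }

  ## --- meta ---------------------------------------------------------
  if (on_stage("meta")) {
    if (is.null(de_res)) stopf("meta stage requires the de stage")
    run_stage("meta", function() {
      mp <- config$meta %||% list()
      contrast <- mp$contrast %||% unique(samples$region)[1]
      ## replication study: an independent single-region dataset
      sim_args <- config$simulate %||% list()
      sim_args$regions <- contrast
      sim_args$region_sampling_prob <- 1
      sim_args$seed <- derive_seed(seed, "meta-replication")
      rep_dat <- generate_bulk_dataset(do.call(sim_config, sim_args))
      rep_de <- run_de_analysis(rep_dat$counts, rep_dat$samples,
                                rep_dat$genes, n_sv = 0,
                                seed = derive_seed(seed, "meta-de"))
      ta <- de_res$de[de_res$de$contrast == contrast, ]
      tb <- rep_de$de[rep_de$de$contrast == contrast, ]
      mt <- meta_analysis(ta, tb, mc_reps = mp$mc_reps %||% 1e5,
                          seed = derive_seed(seed, "meta"))
      write_tsv(mt, file.path(outdir, "meta.tsv"))
      emit("meta", file.path(outdir, "meta.tsv"))
      results$meta <<- mt
    })
  }

  ## --- enrichment ---------------------------------------------------
  if (on_stage("enrichment")) {
    if (is.null(de_res)) stopf("enrichment stage requires the de stage")
    run_stage("enrichment", function() {
      ep <- config$enrichment %||% list()
      contrast <- ep$contrast %||% "Omnibus"
      det <- de_res$de[de_res$de$contrast == contrast, ]
      degs <- split_by_direction(det)
      universe <- det$gene_id
      sets <- generate_gene_sets(
        genes, setNames(det$AveExpr, det$gene_id),
        set_specs = list(
          random = list(size = min(ep$set_size %||% 100, length(universe))),
          high_expressed = list(size = min(ep$set_size %||% 100,
                                           length(universe)),
                                quantile_range = c(0.75, 1))),
        seed = derive_seed(seed, "genesets"))
      rows <- list()
      for (snm in names(sets)) {
        for (dnm in names(degs)) {
          ov <- fisher_overlap(sets[[snm]], degs[[dnm]], universe)
          rows[[length(rows) + 1L]] <- data.frame(
            set = snm, deg_set = dnm, a = ov$a, b = ov$b, c = ov$c,
            d = ov$d, odds_ratio = ov$odds_ratio, p = ov$p,
            stringsAsFactors = FALSE)
        }
      }
      tab <- do.call(rbind, rows)
      write_tsv(tab, file.path(outdir, "enrichment.tsv"))
      emit("enrichment", file.path(outdir, "enrichment.tsv"))
      write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
      emit("enrichment", file.path(outdir, "gene_sets.gmt"))
      results$enrichment <<- tab
    })
  }

  ## --- cellscore ----------------------------------------------------
  if (on_stage("cellscore")) {
    if (is.null(de_res)) stopf("cellscore stage requires the de stage")
    run_stage("cellscore", function() {
      cp <- config$cellscore %||% list()
      sc <- generate_snrna_dataset(sc_config(
        n_cells = cp$n_cells %||% 1000, n_genes = cp$n_genes %||% 600,
        seed = derive_seed(seed, "cellscore-sim")))
      det <- de_res$de[de_res$de$contrast == "Omnibus", ]
      ## map bulk gene ids onto the single-cell gene namespace by rank
      det <- det[order(det$P.Value), ]
      n_map <- min(nrow(det), nrow(sc$counts))
      det <- det[seq_len(n_map), ]
      det$gene_id <- rownames(sc$counts)[seq_len(n_map)]
      gs <- build_weighted_geneset(det, "female_up",
                                   top_n = cp$top_n %||% 200)
      scores <- score_cells(sc$counts, gs, n_ctrl = cp$n_ctrl %||% 200,
                            min_genes_per_cell = 50,
                            seed = derive_seed(seed, "cellscore"))
      labels <- sc$truth$cell_type[match(scores$cell_id,
                                         sc$truth$cell_id)]
      gt <- group_tests(scores, labels)
      write_tsv(data.frame(cell_id = scores$cell_id, raw = scores$raw,
                           normalized = scores$normalized,
                           empirical_p = scores$empirical_p),
                file.path(outdir, "cell_scores.tsv"))
      write_tsv(gt, file.path(outdir, "cell_group_tests.tsv"))
      emit("cellscore", file.path(outdir, "cell_scores.tsv"))
      emit("cellscore", file.path(outdir, "cell_group_tests.tsv"))
      results$cellscore <<- list(scores = scores, groups = gt)
    })
  }

  list(manifest = manifest, results = results, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline input files
#'
#' Checks a counts TSV, a sample table and a gene annotation table for
#' schema problems: duplicate identifiers, identifier mismatches across
#' files, and negative or non-finite count entries.  Returns every
#' violation found rather than stopping at the first.
#'
#' @param counts_path,samples_path,genes_path Paths to the TSV files
#'   (any may be NULL to skip its checks).
#' @return data.frame with columns `file`, `problem` (empty when all
#'   checks pass).
#' @export
validate_inputs <- function(counts_path = NULL, samples_path = NULL,
                            genes_path = NULL) {
  problems <- list()
  note <- function(file, problem) {
    problems[[length(problems) + 1L]] <<- data.frame(
      file = file, problem = problem, stringsAsFactors = FALSE)
  }
  read_or_note <- function(path, reader) {
    tryCatch(suppressWarnings(reader(path)), error = function(e) {
      stopf("cannot read '%s': %s", path, conditionMessage(e))
    })
  }
  counts <- samples <- genes <- NULL
  if (!is.null(counts_path)) {
    df <- read_or_note(counts_path, read_tsv)
    ids <- df[[1]]
    if (anyDuplicated(ids)) note(counts_path, "duplicate gene identifiers")
    m <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
    if (nrow(bad)) {
      for (i in seq_len(min(nrow(bad), 20L))) {
        note(counts_path, sprintf(
          "negative or non-finite count at gene %s, sample %s",
          ids[bad[i, 1]], colnames(m)[bad[i, 2]]))
      }
    }
    counts <- m
    rownames(counts) <- ids
  }
  if (!is.null(samples_path)) {
    samples <- read_or_note(samples_path, read_tsv)
    if (!"sample_id" %in% names(samples)) {
      note(samples_path, "missing 'sample_id' column")
    } else {
      if (anyDuplicated(samples$sample_id)) {
        note(samples_path, "duplicate sample identifiers")
      }
      if (!is.null(counts)) {
        missing_in_counts <- setdiff(samples$sample_id, colnames(counts))
        for (s in missing_in_counts) {
          note(samples_path, sprintf(
            "sample '%s' absent from the count matrix", s))
        }
      }
    }
  }
  if (!is.null(genes_path)) {
    genes <- read_or_note(genes_path, read_tsv)
    need <- setdiff(c("gene_id", "chromosome"), names(genes))
    for (n in need) note(genes_path, sprintf("missing '%s' column", n))
    if ("gene_id" %in% names(genes) && anyDuplicated(genes$gene_id)) {
      note(genes_path, "duplicate gene identifiers")
    }
  }
  if (length(problems)) do.call(rbind, problems) else
    data.frame(file = character(0), problem = character(0),
               stringsAsFactors = FALSE)
}
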