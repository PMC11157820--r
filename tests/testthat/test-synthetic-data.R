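test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_donors = 1), "n_donors")
  expect_error(sim_config(male_fraction = 1.2), "male_fraction")
  expect_error(sim_config(n_genes = 5), "n_genes")
  expect_error(sim_config(nb_dispersion_range = c(0, 0.5)),
               "nb_dispersion_range")
  expect_error(sim_config(regions = c("A", "A")), "regions")
})

test_that("identical configs give bit-identical bulk datasets", {
  a <- small_bulk(seed = 7, n_genes = 200, n_donors = 8)
  b <- small_bulk(seed = 7, n_genes = 200, n_donors = 8)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$lfc, b$truth$lfc)
  c2 <- small_bulk(seed = 8, n_genes = 200, n_donors = 8)
  expect_false(identical(a$counts, c2$counts))
})

test_that("sample layout is forced by donors x regions when sampling prob is 1", {
  d <- generate_bulk_dataset(sim_config(
    n_donors = 20, regions = c("A", "B"), region_sampling_prob = 1,
    n_genes = 50, seed = 1))
  expect_equal(nrow(d$samples), 40)
  expect_equal(ncol(d$counts), 40)
  expect_equal(unname(table(d$samples$region)), c(20L, 20L),
               ignore_attr = TRUE)
})

test_that("no autosomal effect is injected when de_fraction_autosomal is 0", {
  d <- generate_bulk_dataset(sim_config(
    n_donors = 6, regions = "A", region_sampling_prob = 1, n_genes = 300,
    de_fraction_autosomal = 0, n_batch_factors = 0, seed = 2))
  auto <- !(d$genes$chromosome %in% c("chrX", "chrY"))
  expect_true(all(d$truth$lfc[auto, ] == 0))
  expect_false(any(d$truth$de[auto, ]))
})

test_that("default effect sizes reproduce a mean absolute linear fold change near 1.158", {
  d <- generate_bulk_dataset(sim_config(seed = 3))
  auto <- !(d$genes$chromosome %in% c("chrX", "chrY"))
  injected <- d$truth$lfc[auto, ]
  injected <- injected[injected != 0]
  expect_gt(length(injected), 100)
  mean_fold <- mean(2^abs(injected))
  expect_lt(abs(mean_fold - 1.158) / 1.158, 0.10)
})

test_that("structural allosomal effects hold: chrY zero in females, escape genes female-up", {
  d <- small_bulk(seed = 4, n_genes = 2000, n_donors = 12,
                  allosomal_fraction = 0.1)
  y <- d$genes$chromosome == "chrY" & !d$genes$par
  females <- d$samples$sex == "Female"
  expect_true(any(y))
  expect_true(all(d$counts[y, females] == 0))
  par <- d$genes$par
  expect_true(all(d$truth$lfc[par, ] < 0))  # male-shifted PAR genes
})

test_that("generated library sizes have roughly the configured coefficient of variation", {
  d <- generate_bulk_dataset(sim_config(
    n_donors = 60, regions = c("A", "B"), region_sampling_prob = 1,
    n_genes = 400, library_size_cv = 0.3, seed = 5))
  lib <- colSums(d$counts)
  cv <- sd(lib) / mean(lib)
  expect_lt(abs(cv - 0.3) / 0.3, 0.25)
})

test_that("single-nucleus cell-type counts follow configured proportions exactly", {
  sc <- generate_snrna_dataset(sc_config(
    n_cells = 400, cell_type_props = c(A = 0.5, B = 0.25, C = 0.25),
    n_genes = 300, seed = 1))
  tab <- table(sc$truth$cell_type)
  expect_equal(unname(tab[c("A", "B", "C")]), c(200L, 100L, 100L),
               ignore_attr = TRUE)
  expect_error(sc_config(n_cells = 0), "n_cells")
})

test_that("marker genes are strongly enriched in their own cell type", {
  sc <- generate_snrna_dataset(sc_config(
    n_cells = 600, n_genes = 400, marker_fold_change = 8, seed = 2))
  cpmm <- sweep(sc$counts, 2, colSums(sc$counts) / 1e6, "/")
  mk <- which(sc$gene_info$marker_of == "Neuron")
  own <- rowMeans(cpmm[mk, sc$truth$cell_type == "Neuron", drop = FALSE])
  other <- rowMeans(cpmm[mk, sc$truth$cell_type != "Neuron", drop = FALSE])
  expect_gt(mean(own) / mean(other), 4)
})

test_that("state labels partition cells and a zero state effect leaves programs flat", {
  sc <- generate_snrna_dataset(sc_config(
    n_cells = 500, n_genes = 400, n_states_per_type = 2,
    state_effect_log2 = 0, seed = 3))
  expect_true(all(sc$truth$state %in% 1:2))
  pg <- which(sc$gene_info$program_of == "Neuron")
  neu <- sc$truth$cell_type == "Neuron"
  m1 <- mean(sc$counts[pg, neu & sc$truth$state == 1])
  m2 <- mean(sc$counts[pg, neu & sc$truth$state == 2])
  expect_lt(abs(log2(m1 / m2)), 0.1)
})

test_that("gene sets honour size, chromosome composition and expression bias", {
  set.seed(1)
  ann <- data.frame(
    gene_id = sprintf("g%04d", 1:1000),
    chromosome = c(rep("chrX", 60), rep("chr1", 940)),
    stringsAsFactors = FALSE)
  expr_ref <- setNames(rnorm(1000, 5, 2), ann$gene_id)

  sets <- generate_gene_sets(ann, expr_ref, set_specs = list(
    autism_like = list(size = 211, n_chrx = 21),
    unbiased = list(size = 100),
    top_decile = list(size = 50, quantile_range = c(0.9, 1))), seed = 4)

  expect_length(sets$autism_like, 211)
  expect_equal(sum(ann$chromosome[match(sets$autism_like, ann$gene_id)]
                   == "chrX"), 21)
  ## unbiased draw sits within one generator-SE of the background mean
  se <- sd(expr_ref) / sqrt(100)
  expect_lt(abs(mean(expr_ref[sets$unbiased]) - mean(expr_ref)), 2 * se)
  expect_gt(mean(expr_ref[sets$top_decile]), mean(expr_ref))
  ## reproducible under seed
  sets2 <- generate_gene_sets(ann, expr_ref, set_specs = list(
    autism_like = list(size = 211, n_chrx = 21),
    unbiased = list(size = 100),
    top_decile = list(size = 50, quantile_range = c(0.9, 1))), seed = 4)
  expect_identical(sets, sets2)
  expect_error(generate_gene_sets(ann, expr_ref, set_specs = list(
    bad = list(size = 100, n_chrx = 90)), seed = 1), "infeasible")
})
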