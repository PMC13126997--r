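test_that("signatures have exclusive markers and normalized profiles", {
  sig <- generate_signatures(10, 20, 2000, seed = 1)
  expect_equal(nrow(sig$signature_matrix), 2200)
  expect_equal(sum(lengths(sig$marker_map)), 200)
  expect_equal(unname(colSums(sig$signature_matrix)), rep(1, 10), tolerance = 1e-12)
  # every marker has zero mean in every non-assigned type
  for (tp in names(sig$marker_map)) {
    others <- setdiff(colnames(sig$signature_matrix), tp)
    expect_true(all(sig$signature_matrix[sig$marker_map[[tp]], others] == 0))
  }
  sig2 <- generate_signatures(10, 20, 2000, seed = 1)
  expect_identical(sig$signature_matrix, sig2$signature_matrix)
  expect_identical(sig$gene_lengths, sig2$gene_lengths)
  expect_error(generate_signatures(10, 20, 2000, gene_cap = 100),
               class = "lumi_validation_error")
})

test_that("composition rows sum to one and truth validates", {
  comp <- default_composition(include_cep = TRUE)
  sums <- tapply(comp$fraction, paste(comp$group, comp$compartment), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # AAM trajectory in the lumen as designed
  aam <- comp[comp$cell_type == "AAM" & comp$compartment == "LAC", ]
  expect_equal(aam$fraction[match(c("CTRL", "DEP", "HDM", "DH"), aam$group)],
               c(0.02, 0.05, 0.15, 0.35))
  sig <- generate_signatures(10, 5, 100, seed = 1)
  bad <- comp; bad$fraction[1] <- bad$fraction[1] + 0.01
  expect_error(synthetic_truth(sig, bad), class = "lumi_validation_error")
  expect_error(synthetic_truth(sig, comp, dispersion = 0),
               class = "lumi_validation_error")
  expect_error(synthetic_truth(sig, comp, synergy_genes = "NotAGene"),
               class = "lumi_validation_error")
})

test_that("bulk sample means match the analytic NB means at low dispersion", {
  sig <- generate_signatures(4, 5, 200, seed = 2)
  comp <- tidyr::crossing(group = "CTRL", compartment = "LAC",
                          cell_type = colnames(sig$signature_matrix)) |>
    dplyr::mutate(fraction = 0.25)
  truth <- synthetic_truth(sig, comp, dispersion = 1e-4,
                           library_size_range = c(1e6, 1e6), seed = 2)
  bulk <- generate_bulk(truth, n_replicates = 10, seed = 2)
  expected <- 1e6 * expected_relative_expression(truth, "CTRL", "LAC")
  observed <- rowMeans(bulk$counts)
  rel_err <- abs(observed - expected) / expected
  expect_lt(mean(rel_err), 0.02)
})

test_that("zero composition zeroes exclusive markers; seeds reproduce bulk", {
  sig <- generate_signatures(2, 5, 50, seed = 3, type_names = c("X", "Y"))
  comp <- tibble::tibble(group = "CTRL", compartment = "LAC",
                         cell_type = c("X", "Y"), fraction = c(0, 1))
  truth <- synthetic_truth(sig, comp, seed = 3, library_size_range = c(1e5, 1e5))
  bulk <- generate_bulk(truth, n_replicates = 3, seed = 3)
  expect_true(all(bulk$counts[truth$marker_map$X, ] == 0))
  bulk2 <- generate_bulk(truth, n_replicates = 3, seed = 3)
  expect_identical(bulk$counts, bulk2$counts)
  expect_error(expected_relative_expression(truth, "HDM", "LAC"),
               class = "lumi_validation_error")
})

test_that("single-cell draws respect composition, depth and seed", {
  sig <- generate_signatures(2, 5, 50, seed = 4, type_names = c("X", "Y"))
  comp <- tibble::tibble(group = "HDM", compartment = "LAC",
                         cell_type = c("X", "Y"), fraction = c(0.5, 0.5))
  truth <- synthetic_truth(sig, comp, seed = 4)
  sc <- generate_sc(truth, cells_per_sample = 1000, molecules_per_cell = 5000,
                    seed = 4, design = tibble::tibble(sample_id = "s1", group = "HDM"))
  # every cell's raw total equals the multinomial trial count
  expect_true(all(Matrix::rowSums(sc$counts) == 5000))
  # type split within the binomial 99% CI
  nx <- sum(sc$cells$cell_type == "X")
  ci <- qbinom(c(0.005, 0.995), 1000, 0.5)
  expect_gte(nx, ci[1]); expect_lte(nx, ci[2])
  sc2 <- generate_sc(truth, cells_per_sample = 1000, molecules_per_cell = 5000,
                     seed = 4, design = tibble::tibble(sample_id = "s1", group = "HDM"))
  expect_identical(as.matrix(sc$counts), as.matrix(sc2$counts))
  expect_identical(sc$sample_totals, sc2$sample_totals)
})

test_that("LR wiring uses synergy genes for true pairs and is reproducible", {
  st <- small_study()
  lr <- st$lr_pairs
  expect_equal(nrow(lr), 25)
  expect_true(all(c(lr$ligand, lr$receptor) %in% rownames(st$truth$signature_matrix)))
  is_true <- attr(lr, "is_true")
  expect_true(all(lr$ligand[is_true] %in% st$truth$synergy_genes))
  expect_true(all(lr$receptor[is_true] %in% st$truth$synergy_genes))
  expect_false(any(lr$ligand[!is_true] %in% st$truth$synergy_genes))
  lr2 <- generate_lr_table(st$truth, 5, 20, seed = st$truth$seed)
  expect_identical(lr2$ligand, lr$ligand)
  expect_error(generate_lr_table(st$truth, n_true_pairs = 1000, 5),
               class = "lumi_validation_error")
})

test_that("make_study yields a consistent, reproducible bundle", {
  st <- small_study()
  expect_equal(ncol(st$bulk$counts), 4 * 2 * 3)  # groups x compartments x reps
  expect_equal(length(st$markers), 10)
  st2 <- suppressWarnings(make_study(small_config(), seed = 101))
  expect_identical(st$bulk$counts, st2$bulk$counts)
  st3 <- suppressWarnings(make_study(small_config(), seed = 102))
  expect_identical(dim(st3$bulk$counts), dim(st$bulk$counts))
  expect_false(identical(st3$bulk$counts, st$bulk$counts))
  expect_error(study_config(not_a_key = 1), class = "lumi_config_error")
})

test_that("YAML config round-trips and rejects unknown keys", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_replicates: 4", "dispersion: 0.2"), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$n_replicates, 4)
  expect_equal(cfg$dispersion, 0.2)
  writeLines("mystery_knob: 3", path)
  expect_error(read_study_config(path), class = "lumi_config_error")
})

test_that("combination-enhanced truth contains synergy genes and shifted markers", {
  st <- small_study()
  tr <- combination_enhanced_truth(st$truth, fc_threshold = 2)
  expect_true(all(st$truth$synergy_genes %in% tr$gene_id))
  expect_true(all(st$truth$marker_map$AAM %in% tr$gene_id[tr$direction == 1]))
  expect_true(all(st$truth$marker_map$AM %in% tr$gene_id[tr$direction == -1]))
  # eosinophil markers expand under HDM alone, so they are not combination-specific
  expect_false(any(st$truth$marker_map$Eos %in% tr$gene_id))
})
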