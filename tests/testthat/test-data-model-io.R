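test_that("expression matrix reader validates and preserves order", {
  dir <- withr::local_tempdir()
  counts <- tibble::tibble(gene_id = c("gB", "gA", "gC"),
                           s1 = c(3L, 10L, 0L), s2 = c(7L, 2L, 1L))
  readr::write_tsv(counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(tibble::tibble(sample_id = c("s1", "s2"), group = c("CTRL", "DH"),
                                  compartment = "LAC", replicate = 1:2),
                   file.path(dir, "samples.tsv"))
  readr::write_tsv(tibble::tibble(gene_id = c("gA", "gB", "gC"),
                                  length_bp = c(1000L, 500L, 1500L)),
                   file.path(dir, "lengths.tsv"))
  em <- read_expression_matrix(file.path(dir, "counts.tsv"),
                               file.path(dir, "samples.tsv"),
                               file.path(dir, "lengths.tsv"))
  expect_equal(dim(em), c(3L, 2L))
  expect_identical(rownames(em$counts), c("gB", "gA", "gC"))  # file order kept
  expect_equal(unname(em$gene_lengths["gB"]), 500)

  # negative count
  counts$s1[1] <- -1L
  readr::write_tsv(counts, file.path(dir, "counts.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "counts.tsv"),
                                      file.path(dir, "samples.tsv"),
                                      file.path(dir, "lengths.tsv")),
               class = "lumi_validation_error")

  # duplicate gene id
  counts$s1[1] <- 3L; counts$gene_id[2] <- "gB"
  readr::write_tsv(counts, file.path(dir, "counts.tsv"))
  expect_error(read_expression_matrix(file.path(dir, "counts.tsv"),
                                      file.path(dir, "samples.tsv"),
                                      file.path(dir, "lengths.tsv")),
               class = "lumi_format_error")
})

test_that("sample sheet problems are rejected, never repaired", {
  em <- toy_matrix()
  sheet <- em$samples
  sheet$compartment[2] <- NA
  expect_error(expression_matrix(em$counts, em$gene_lengths, sheet),
               class = "lumi_validation_error")
  sheet <- em$samples; sheet$group[1] <- "MOCK"
  expect_error(expression_matrix(em$counts, em$gene_lengths, sheet),
               class = "lumi_validation_error")
  dup <- dplyr::bind_rows(em$samples, em$samples[1, ])
  expect_error(expression_matrix(cbind(em$counts, em$counts[, 1]),
                                 em$gene_lengths, dup),
               class = "lumi_validation_error")
})

test_that("GMT reader builds sets, dedups genes, rejects bad lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("AAM\tdesc\tArg1\tChil3\tRetnla",
               "Eos\tdesc\tPrg2\tEpx"), path)
  sets <- read_marker_gmt(path)
  expect_length(sets, 2)
  expect_setequal(sets$AAM, c("Arg1", "Chil3", "Retnla"))

  writeLines(c("AAM\tdesc\tArg1\tArg1\tChil3"), path)
  expect_warning(sets <- read_marker_gmt(path), "deduplicated")
  expect_length(sets$AAM, 2)

  writeLines(c("AAM\tdesc\tArg1", "AAM\tdesc\tChil3"), path)
  expect_error(read_marker_gmt(path), class = "lumi_validation_error")

  writeLines("AAM\tdesc", path)
  expect_error(suppressWarnings(read_marker_gmt(path)))
})

test_that("LR table reader validates pairs and rejects complexes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pair_id,ligand,receptor", "P1,Ccl8,Ccr8"), path)
  tab <- read_lr_table(path)
  expect_equal(nrow(tab), 1)
  expect_identical(tab$ligand, "Ccl8")

  writeLines(c("pair_id,ligand,receptor", "P1,Ccl8,"), path)
  expect_error(read_lr_table(path), class = "lumi_validation_error")

  writeLines(c("pair_id,ligand,receptor", "P1,Ccl8,Ccr8", "P1,Ccl2,Ccr2"), path)
  expect_error(read_lr_table(path), class = "lumi_validation_error")

  writeLines(c("pair_id,ligand,receptor", "PC,Il4,Il4ra_Il13ra1"), path)
  expect_error(read_lr_table(path), regexp = "PC", class = "lumi_format_error")
})

test_that("results tables round-trip and are byte-deterministic", {
  tab <- tibble::tibble(gene_id = c("b", "a"), des = c(1.23456789, -2.5),
                        n = c(3L, 4L))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(tab, p1, sort_by = "gene_id")
  write_results_table(tab, p2, sort_by = "gene_id")
  expect_identical(readLines(p1), readLines(p2))
  back <- read_results_table(p1)
  expect_equal(back$des, c(-2.5, 1.23456789), tolerance = 1e-9)
  expect_identical(back$gene_id, c("a", "b"))

  empty <- tab[0, ]
  write_results_table(empty, p1)
  expect_identical(readLines(p1), "gene_id\tdes\tn")
})

test_that("expression matrix and single-cell dataset round-trip through disk", {
  em <- small_study()$bulk
  dir <- withr::local_tempdir()
  write_expression_matrix(em, dir)
  back <- read_expression_matrix(file.path(dir, "counts.tsv"),
                                 file.path(dir, "samples.tsv"),
                                 file.path(dir, "lengths.tsv"))
  expect_identical(unname(back$counts), unname(em$counts))
  expect_identical(rownames(back$counts), rownames(em$counts))
  expect_equal(back$samples, em$samples, ignore_attr = TRUE)

  sc <- small_study()$sc
  scdir <- withr::local_tempdir()
  write_sc_dataset(sc, scdir)
  back_sc <- read_sc_dataset(file.path(scdir, "counts.mtx"),
                             file.path(scdir, "genes.txt"),
                             file.path(scdir, "barcodes.txt"),
                             file.path(scdir, "cells.tsv"),
                             file.path(scdir, "lavage_totals.tsv"))
  expect_equal(as.matrix(back_sc$counts), as.matrix(sc$counts), ignore_attr = FALSE)
  expect_equal(back_sc$cells$cell_type, sc$cells$cell_type)
})

test_that("ortholog map reader requires source/target columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("source,target", "CCL8,Ccl8"), path)
  m <- read_ortholog_map(path)
  expect_identical(m$target, "Ccl8")
  writeLines(c("a,b", "CCL8,Ccl8"), path)
  expect_error(read_ortholog_map(path), class = "lumi_format_error")
})
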