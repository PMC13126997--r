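#' Single-cell molecule-count dataset
#'
#' Container for deduplicated, error-corrected molecule counts per cell
#' (cells x genes), per-cell annotations (cell type, sample, treatment
#' group) and per-sample total lavage cell counts used for per-lung
#' absolute scaling.
#'
#' @param counts Non-negative integer matrix or sparse `Matrix`, cells in
#'   rows (rownames are cell ids), genes in columns.
#' @param cells Data frame with columns `cell_id`, `cell_type`, `sample_id`,
#'   `group`; one row per row of `counts`, in order.
#' @param sample_totals Data frame with columns `sample_id`,
#'   `total_lavage_cells_per_lung` (non-negative integers from the
#'   haemocytometer lavage count). May omit samples; per-lung scaling then
#'   skips them with a warning.
#' @param cell_type_levels Controlled vocabulary for `cell_type`; defaults
#'   to the labels present.
#' @return An object of class `sc_dataset` with elements `counts`, `cells`,
#'   `sample_totals` and optionally `normalized` (set by
#'   [normalize_per_cell()]).
#' @export
sc_dataset <- function(counts, cells, sample_totals, cell_type_levels = NULL) {
  if (!inherits(counts, "CsparseMatrix")) {
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    abort("Molecule counts must be non-negative whole numbers.", class = "lumi_validation_error")
  }
  cells <- as_tibble(cells)
  need <- c("cell_id", "cell_type", "sample_id", "group")
  if (!all(need %in% names(cells))) {
    abort("Cell annotations need columns cell_id, cell_type, sample_id, group.",
          class = "lumi_validation_error")
  }
  if (nrow(cells) != nrow(counts)) {
    abort("Cell annotations must cover every cell, in order.", class = "lumi_validation_error")
  }
  if (any(is.na(cells$cell_type)) || any(is.na(cells$sample_id))) {
    abort("Cell annotations must cover all cells (no NA cell_type/sample_id).",
          class = "lumi_validation_error")
  }
  if (is.null(cell_type_levels)) cell_type_levels <- sort(unique(cells$cell_type))
  bad <- setdiff(unique(cells$cell_type), cell_type_levels)
  if (length(bad)) {
    abort(paste0("Cell type label(s) outside the declared vocabulary: ",
                 paste(bad, collapse = ", ")), class = "lumi_validation_error")
  }
  sample_totals <- as_tibble(sample_totals)
  if (!all(c("sample_id", "total_lavage_cells_per_lung") %in% names(sample_totals))) {
    abort("sample_totals needs columns sample_id and total_lavage_cells_per_lung.",
          class = "lumi_validation_error")
  }
  if (any(sample_totals$total_lavage_cells_per_lung < 0, na.rm = TRUE)) {
    abort("Lavage totals must be non-negative.", class = "lumi_validation_error")
  }
  rownames(counts) <- cells$cell_id
  structure(list(counts = counts, cells = cells, sample_totals = sample_totals,
                 cell_type_levels = cell_type_levels, normalized = NULL),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat("<sc_dataset> ", nrow(x$counts), " cells x ", ncol(x$counts), " genes; ",
      length(unique(x$cells$sample_id)), " samples; ",
      length(x$cell_type_levels), " cell types",
      if (!is.null(x$normalized)) "; normalized" else "", "\n", sep = "")
  invisible(x)
}

#' @describeIn sc_dataset Tidy the per-cell annotations (joined with
#'   per-cell total molecule counts).
#' @param x An `sc_dataset`.
#' @param ... Unused.
#' @export
tidy.sc_dataset <- function(x, ...) {
  out <- x$cells
  out$total_molecules <- Matrix::rowSums(x$counts)
  dplyr::left_join(out, x$sample_totals, by = "sample_id")
}

#' Remove cells with zero total molecules
#'
#' Zero-total cells cannot be depth-normalized; they are dropped here, with
#' a warning, before [normalize_per_cell()].
#'
#' @param sc An [sc_dataset()].
#' @return The dataset without zero-total cells.
#' @export
remove_empty_cells <- function(sc) {
  stopifnot(inherits(sc, "sc_dataset"))
  tot <- Matrix::rowSums(sc$counts)
  if (any(tot == 0)) {
    warn(paste0("Removing ", sum(tot == 0), " cell(s) with zero total molecules."))
    sc$counts <- sc$counts[tot > 0, , drop = FALSE]
    sc$cells <- sc$cells[tot > 0, ]
  }
  sc
}

#' Read single-cell counts from an MTX triple
#'
#' Reads a MatrixMarket sparse counts matrix with sidecar gene-id and
#' cell-barcode files (one id per line), plus cell annotation and lavage
#' total TSVs, into an [sc_dataset()]. The MTX is stored genes x cells (the
#' de facto convention) and transposed on read.
#'
#' @param mtx_path MatrixMarket file, genes in rows.
#' @param genes_path,cells_path One id per line, matching MTX dimensions.
#' @param annotations_path TSV with columns `cell_id`, `cell_type`,
#'   `sample_id`, `group`.
#' @param totals_path TSV with columns `sample_id`,
#'   `total_lavage_cells_per_lung`.
#' @return An [sc_dataset()].
#' @export
read_sc_dataset <- function(mtx_path, genes_path, cells_path, annotations_path, totals_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- trimws(readLines(genes_path))
  barcodes <- trimws(readLines(cells_path))
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    abort("MTX dimensions do not match sidecar id files.", class = "lumi_format_error")
  }
  m <- Matrix::t(m)
  dimnames(m) <- list(barcodes, genes)
  cells <- read_results_table(annotations_path)
  totals <- read_results_table(totals_path)
  cells <- cells[match(barcodes, cells$cell_id), ]
  sc_dataset(m, cells, totals)
}

#' Write a single-cell dataset as an MTX triple plus annotation TSVs
#'
#' @param sc An [sc_dataset()].
#' @param dir Output directory (created if needed). Writes `counts.mtx`
#'   (genes x cells), `genes.txt`, `barcodes.txt`, `cells.tsv`,
#'   `lavage_totals.tsv`.
#' @return Invisibly, `dir`.
#' @export
write_sc_dataset <- function(sc, dir) {
  stopifnot(inherits(sc, "sc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(sc$counts), file.path(dir, "counts.mtx"))
  writeLines(colnames(sc$counts), file.path(dir, "genes.txt"))
  writeLines(rownames(sc$counts), file.path(dir, "barcodes.txt"))
  write_results_table(sc$cells, file.path(dir, "cells.tsv"))
  write_results_table(sc$sample_totals, file.path(dir, "lavage_totals.tsv"))
  invisible(dir)
}
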