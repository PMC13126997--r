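#' Read a bulk expression study from disk
#'
#' Reads a gene x sample counts table (TSV or CSV, gene ids in the first
#' column), a sample sheet (`sample_id`, `group`, `compartment`, `replicate`)
#' and a per-gene length table (`gene_id`, `length_bp`), validates them and
#' assembles an [expression_matrix()]. Row and column order are preserved
#' from the files. Gene ids are matched case-sensitively after trimming
#' surrounding whitespace, the package's single identifier normalization.
#'
#' @param counts_path,samplesheet_path,lengths_path File paths.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(counts_path, samplesheet_path, lengths_path) {
  counts_df <- read_delim_auto(counts_path)
  gene_ids <- trimws(as.character(counts_df[[1]]))
  if (anyDuplicated(gene_ids)) {
    abort(paste0("Duplicate gene id in ", counts_path, ": ",
                 gene_ids[duplicated(gene_ids)][1]), class = "lumi_format_error")
  }
  mat <- as.matrix(counts_df[, -1, drop = FALSE])
  if (!is.numeric(mat)) abort("Counts must be numeric.", class = "lumi_validation_error")
  rownames(mat) <- gene_ids
  sheet <- read_delim_auto(samplesheet_path)
  lengths_df <- read_delim_auto(lengths_path)
  if (!all(c("gene_id", "length_bp") %in% names(lengths_df))) {
    abort("Lengths file needs columns gene_id and length_bp.", class = "lumi_format_error")
  }
  lens <- stats::setNames(lengths_df$length_bp, trimws(lengths_df$gene_id))
  expression_matrix(mat, lens, sheet)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "lumi_io_error")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
}

#' Marker gene sets for cell-type interpolation
#'
#' A named collection of cell-type marker gene lists, as curated from
#' literature, Immgen and lung cell atlases. Overlap between sets is allowed
#' but reported with a warning, never silently accepted.
#'
#' @param sets Named list of character vectors of gene ids; every set
#'   non-empty, names unique.
#' @param provenance Optional named character vector of per-set notes.
#' @return An object of class `marker_set_collection` (a named list).
#' @export
marker_set_collection <- function(sets, provenance = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("Every marker set needs a name.", class = "lumi_validation_error")
  }
  if (anyDuplicated(names(sets))) {
    abort(paste0("Duplicate marker set name: ", names(sets)[duplicated(names(sets))][1]),
          class = "lumi_validation_error")
  }
  sets <- lapply(sets, function(g) trimws(as.character(g)))
  sizes <- lengths(sets)
  if (any(sizes == 0)) {
    abort(paste0("Empty marker set: ", names(sets)[sizes == 0][1]),
          class = "lumi_validation_error")
  }
  deduped <- lapply(sets, unique)
  ndup <- sum(lengths(sets) - lengths(deduped))
  if (ndup > 0) warn(paste0(ndup, " duplicated gene(s) within marker sets were deduplicated."))
  all_genes <- unlist(deduped, use.names = FALSE)
  shared <- unique(all_genes[duplicated(all_genes)])
  if (length(shared)) {
    warn(paste0(length(shared), " gene(s) appear in more than one marker set, e.g. ", shared[1],
                "; they will contribute to each set they belong to."))
  }
  structure(deduped, provenance = provenance, class = "marker_set_collection")
}

#' Read marker gene sets from a GMT file
#'
#' GMT lines carry a set name, a description and then member gene ids,
#' tab-separated. Duplicate genes within a set are deduplicated with a
#' warning; a duplicated set name or an empty gene list is an error.
#'
#' @param path GMT file path.
#' @return A [marker_set_collection()].
#' @export
read_marker_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path), class = "lumi_io_error")
  sets <- fgsea::gmtPathways(path)
  marker_set_collection(sets)
}

#' @export
print.marker_set_collection <- function(x, ...) {
  cat("<marker_set_collection> ", length(x), " sets, ",
      length(unique(unlist(x))), " distinct genes\n", sep = "")
  invisible(x)
}

#' @describeIn marker_set_collection Tidy to a (cell_type, gene_id) tibble.
#' @param x A `marker_set_collection`.
#' @param ... Unused.
#' @export
tidy.marker_set_collection <- function(x, ...) {
  tibble(cell_type = rep(names(x), lengths(x)),
         gene_id = unlist(x, use.names = FALSE))
}

#' Ligand-receptor pair table
#'
#' CellPhoneDB-style table of curated signalling pairs. Multi-subunit
#' complexes are out of scope and rejected loudly by [read_lr_table()].
#'
#' @param pairs Data frame with columns `pair_id`, `ligand`, `receptor` and
#'   optionally `species_source` (`native` or `ortholog-mapped`).
#' @return A tibble of class `lr_pair_table`.
#' @export
lr_pair_table <- function(pairs) {
  pairs <- as_tibble(pairs)
  need <- c("pair_id", "ligand", "receptor")
  if (!all(need %in% names(pairs))) {
    abort("Pair table needs columns pair_id, ligand, receptor.", class = "lumi_format_error")
  }
  if (!"species_source" %in% names(pairs)) pairs$species_source <- "native"
  pairs$ligand <- trimws(pairs$ligand)
  pairs$receptor <- trimws(pairs$receptor)
  if (any(is.na(pairs$ligand) | pairs$ligand == "" |
          is.na(pairs$receptor) | pairs$receptor == "")) {
    abort("Every pair needs a non-empty ligand and receptor gene id.",
          class = "lumi_validation_error")
  }
  if (anyDuplicated(pairs$pair_id)) {
    abort(paste0("Duplicate pair_id: ", pairs$pair_id[duplicated(pairs$pair_id)][1]),
          class = "lumi_validation_error")
  }
  bad <- setdiff(unique(pairs$species_source), c("native", "ortholog-mapped"))
  if (length(bad)) abort("species_source must be 'native' or 'ortholog-mapped'.",
                         class = "lumi_validation_error")
  class(pairs) <- c("lr_pair_table", class(pairs))
  pairs
}

#' Read a ligand-receptor pair table from CSV
#'
#' @param path CSV with header columns `pair_id`, `ligand`, `receptor`.
#' @param complex_delim Delimiter marking multi-subunit complex members in a
#'   gene field; rows containing it are rejected with the offending
#'   `pair_id` named, since complex semantics are out of scope.
#' @return An [lr_pair_table()].
#' @export
read_lr_table <- function(path, complex_delim = "_") {
  df <- read_delim_auto(path)
  tab <- lr_pair_table(df)
  is_complex <- grepl(complex_delim, tab$ligand, fixed = TRUE) |
    grepl(complex_delim, tab$receptor, fixed = TRUE)
  if (any(is_complex)) {
    abort(paste0("Multi-subunit complex pairs are not supported: ",
                 paste(tab$pair_id[is_complex], collapse = ", ")),
          class = "lumi_format_error")
  }
  tab
}

#' Write a results table as TSV
#'
#' Writes any tabular result with a header line; floating-point values keep
#' full (>= 6 significant digit) precision. Row order is deterministic:
#' either the table's existing order (tables produced by this package are
#' already sorted by a documented key) or an explicit `sort_by` column.
#'
#' @param table A data frame.
#' @param path Output path.
#' @param sort_by Optional column name to sort on (ascending) before writing.
#' @return Invisibly, the path.
#' @export
write_results_table <- function(table, path, sort_by = NULL) {
  table <- as_tibble(table)
  if (!is.null(sort_by)) table <- dplyr::arrange(table, .data[[sort_by]])
  # list-columns (e.g. genes_missing) are flattened to comma-joined strings
  is_list <- vapply(table, is.list, logical(1))
  table[is_list] <- lapply(table[is_list], function(col) {
    vapply(col, function(v) paste(v, collapse = ","), character(1))
  })
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write a bulk expression study to a directory
#'
#' Writes `counts.tsv` (gene ids in the first column), `samples.tsv` and
#' `lengths.tsv`, the triple [read_expression_matrix()] reads back.
#'
#' @param em An [expression_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_expression_matrix <- function(em, dir) {
  stopifnot(inherits(em, "expression_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts_df <- dplyr::bind_cols(tibble(gene_id = rownames(em$counts)),
                                as_tibble(em$counts))
  readr::write_tsv(counts_df, file.path(dir, "counts.tsv"), progress = FALSE)
  write_results_table(em$samples, file.path(dir, "samples.tsv"))
  write_results_table(tibble(gene_id = names(em$gene_lengths),
                             length_bp = unname(em$gene_lengths)),
                      file.path(dir, "lengths.tsv"))
  invisible(dir)
}

#' Read an ortholog symbol map from CSV
#'
#' @param path CSV with columns `source`, `target` (e.g. human symbol to
#'   murine symbol).
#' @return A tibble with columns `source`, `target`.
#' @export
read_ortholog_map <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("source", "target") %in% names(df))) {
    abort("Ortholog map needs columns source and target.", class = "lumi_format_error")
  }
  as_tibble(df[c("source", "target")])
}
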