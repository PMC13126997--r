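#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr %>%
NULL

#' Treatment-group and compartment vocabularies
#'
#' Treatment arms of the two-particle co-exposure design: vehicle control
#' (CTRL), diesel exhaust particles alone (DEP), house dust mite alone (HDM),
#' their combination (DH), cerium-oxide nanoparticles alone (CEP) and their
#' combination with HDM (CH). Compartments are luminal airway cells recovered
#' by lavage (LAC) and post-lavage lung tissue (TISS).
#'
#' @format Character vectors.
#' @export
group_levels <- c("CTRL", "DEP", "HDM", "DH", "CEP", "CH")

#' @rdname group_levels
#' @export
compartment_levels <- c("LAC", "TISS")

#' Bulk expression matrix with sample design
#'
#' Container for gene-level bulk RNA-seq counts: an integer genes x samples
#' matrix, per-gene transcript lengths (bp) and a sample sheet assigning each
#' sample to a treatment group, compartment and replicate.
#'
#' @param counts Integer matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). Counts must be
#'   non-negative whole numbers.
#' @param gene_lengths Positive integer vector of transcript lengths in bp,
#'   one per gene, named by gene id (or in row order).
#' @param samples Data frame with columns `sample_id`, `group`,
#'   `compartment`, `replicate`; one row per column of `counts`, in order.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `counts`, `gene_lengths` and `samples` (a tibble).
#' @export
expression_matrix <- function(counts, gene_lengths, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) abort("`counts` must have gene ids as rownames.", class = "lumi_validation_error")
  if (anyDuplicated(rownames(counts))) {
    abort("Duplicate gene ids in counts matrix.", class = "lumi_format_error")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative whole numbers with no missing values.",
          class = "lumi_validation_error")
  }
  samples <- as_tibble(samples)
  required <- c("sample_id", "group", "compartment", "replicate")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort(paste0("Sample sheet is missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "lumi_validation_error")
  }
  if (nrow(samples) != ncol(counts)) {
    abort("Sample sheet rows must match count matrix columns.", class = "lumi_validation_error")
  }
  if (!is.null(colnames(counts)) && !identical(as.character(samples$sample_id), colnames(counts))) {
    abort("Sample ids in the sheet must match count matrix columns, in order.",
          class = "lumi_validation_error")
  }
  colnames(counts) <- samples$sample_id
  if (any(is.na(samples$group)) || any(is.na(samples$compartment))) {
    abort("Every sample needs a group and a compartment.", class = "lumi_validation_error")
  }
  bad_grp <- setdiff(unique(samples$group), group_levels)
  if (length(bad_grp)) {
    abort(paste0("Unknown treatment group(s): ", paste(bad_grp, collapse = ", ")),
          class = "lumi_validation_error")
  }
  bad_cmp <- setdiff(unique(samples$compartment), compartment_levels)
  if (length(bad_cmp)) {
    abort(paste0("Unknown compartment(s): ", paste(bad_cmp, collapse = ", ")),
          class = "lumi_validation_error")
  }
  key <- paste(samples$group, samples$compartment, samples$replicate)
  if (anyDuplicated(key)) {
    abort("(group, compartment, replicate) must be unique across samples.",
          class = "lumi_validation_error")
  }
  gene_lengths <- normalize_gene_lengths(gene_lengths, rownames(counts))
  structure(list(counts = counts, gene_lengths = gene_lengths, samples = samples),
            class = "expression_matrix")
}

normalize_gene_lengths <- function(gene_lengths, gene_ids) {
  if (is.null(names(gene_lengths))) {
    if (length(gene_lengths) != length(gene_ids)) {
      abort("gene_lengths must cover every gene.", class = "lumi_validation_error")
    }
    names(gene_lengths) <- gene_ids
  } else {
    missing <- setdiff(gene_ids, names(gene_lengths))
    if (length(missing)) {
      abort(paste0("gene_lengths missing for ", length(missing), " gene(s), e.g. ",
                   missing[1]), class = "lumi_validation_error")
    }
    gene_lengths <- gene_lengths[gene_ids]
  }
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
    abort("Gene lengths must be positive.", class = "lumi_validation_error")
  }
  gene_lengths
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$counts), " genes x ", ncol(x$counts), " samples\n", sep = "")
  cat("  groups: ", paste(unique(x$samples$group), collapse = ", "),
      "; compartments: ", paste(unique(x$samples$compartment), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Subset an expression matrix to samples matching a design condition
#'
#' @param em An [expression_matrix()].
#' @param group,compartment Optional filters; `NULL` keeps all.
#' @return An `expression_matrix` restricted to the matching samples.
#' @export
filter_samples <- function(em, group = NULL, compartment = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- rep(TRUE, nrow(em$samples))
  if (!is.null(group)) keep <- keep & em$samples$group %in% group
  if (!is.null(compartment)) keep <- keep & em$samples$compartment %in% compartment
  if (!any(keep)) abort("No samples match the requested condition.", class = "lumi_validation_error")
  expression_matrix(em$counts[, keep, drop = FALSE], em$gene_lengths, em$samples[keep, ])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bulk expression matrix into long form
#'
#' @param x An [expression_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (gene, sample): `gene_id`, `sample_id`,
#'   `group`, `compartment`, `replicate`, `count`, `length_bp`.
#' @export
tidy.expression_matrix <- function(x, ...) {
  long <- as_tibble(x$counts, rownames = "gene_id") %>%
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id", values_to = "count")
  long$length_bp <- unname(x$gene_lengths[long$gene_id])
  dplyr::left_join(long, x$samples, by = "sample_id")
}
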