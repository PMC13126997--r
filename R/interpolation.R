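#' Differential expression score (DES)
#'
#' `DES = log2FC x -log10(q)`: a per-gene effect summary combining the size
#' and the significance of a change. Odd in log2FC; monotone decreasing in
#' q for fixed positive log2FC; zero when log2FC is zero. q-values at or
#' below zero are floored (default 1e-300) so the log never throws.
#'
#' @param log2_fc Numeric log2 fold changes.
#' @param q_value FDR q-values in `(0, 1]` (values below `q_floor` floored).
#' @param q_floor Floor applied before the log.
#' @return Numeric DES, vectorized.
#' @export
compute_des <- function(log2_fc, q_value, q_floor = 1e-300) {
  if (any(q_value > 1, na.rm = TRUE)) {
    abort("q-values must not exceed 1.", class = "lumi_validation_error")
  }
  q <- pmax(q_value, q_floor)
  log2_fc * (-log10(q))
}

#' Cell-type interpolation of a bulk contrast
#'
#' Estimates relative cell-type abundance changes from bulk data as the
#' mean DES over each curated marker set: for each cell type, the mean and
#' SEM of member-gene DES over the genes measured in the contrast.
#' Marker genes missing from the contrast are listed, not errors; a set
#' with no measured gene is dropped with a warning. SEM is the sample
#' standard deviation over genes found divided by sqrt(n found) (0 when
#' n = 1).
#'
#' @param contrast A `contrast_table` (see [run_contrast()]).
#' @param markers A [marker_set_collection()].
#' @return A tibble of class `cell_type_scores`, sorted by `mean_des`
#'   descending: `cell_type`, `mean_des`, `sem_des`, `n_genes_used`,
#'   `genes_missing` (list-column). Attribute `dropped_sets` names sets
#'   with zero measured genes.
#' @export
interpolate_cell_types <- function(contrast, markers) {
  stopifnot(inherits(markers, "marker_set_collection"))
  des <- stats::setNames(contrast$des, contrast$gene_id)
  rows <- list(); dropped <- character(0)
  for (tp in names(markers)) {
    found <- intersect(markers[[tp]], names(des))
    missing <- setdiff(markers[[tp]], names(des))
    if (length(found) == 0) {
      dropped <- c(dropped, tp)
      next
    }
    vals <- des[found]
    rows[[tp]] <- tibble(cell_type = tp,
                         mean_des = mean(vals),
                         sem_des = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
                         n_genes_used = length(vals),
                         genes_missing = list(missing))
  }
  if (length(dropped)) {
    warn(paste0("Marker set(s) with no measured gene dropped: ",
                paste(dropped, collapse = ", ")))
  }
  if (!length(rows)) {
    abort("No marker set has any measured gene in this contrast.",
          class = "lumi_empty_result_error")
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$mean_des))
  structure(out, class = c("cell_type_scores", class(tibble())),
            contrast = attr(contrast, "contrast"), dropped_sets = dropped)
}

#' Compartment difference of DES (delta-DES sort)
#'
#' Computes per-gene DES in the lavage (LAC) and tissue (TISS) runs of the
#' same contrast and their difference `delta = des_lac - des_tiss`, sorted
#' descending by delta (ties broken lexicographically by gene id). Large
#' positive delta marks lumen-dominated responders.
#'
#' @param contrast_lac,contrast_tiss `contrast_table`s for the same
#'   comparison in the two compartments; genes are intersected.
#' @return Tibble (`gene_id`, `des_lac`, `des_tiss`, `delta`), sorted.
#' @export
delta_des <- function(contrast_lac, contrast_tiss) {
  common <- intersect(contrast_lac$gene_id, contrast_tiss$gene_id)
  if (length(common) == 0) {
    abort("The two contrasts share no genes.", class = "lumi_validation_error")
  }
  lac <- stats::setNames(contrast_lac$des, contrast_lac$gene_id)[common]
  tis <- stats::setNames(contrast_tiss$des, contrast_tiss$gene_id)[common]
  out <- tibble(gene_id = common, des_lac = unname(lac), des_tiss = unname(tis),
                delta = unname(lac - tis))
  out[order(-out$delta, out$gene_id), ]
}

#' Marker-set specificity against annotated single-cell data
#'
#' Formalizes the visual marker-specificity check as a score: for each
#' marker gene, specificity = (mean normalized expression in the assigned
#' type) / (sum of mean normalized expression across all types), 0 when the
#' denominator is 0; a set's specificity is the mean over its measured
#' member genes. 1 means exclusively expressed in the assigned type; 1/k
#' means uniform across k types. Set names must match the dataset's cell
#' type labels; unmatched sets are skipped with a warning. Uses per-cell
#' normalized counts (run [normalize_per_cell()] first, or it is applied
#' here at the default target).
#'
#' @param sc An [sc_dataset()] with at least 2 annotated cell types.
#' @param markers A [marker_set_collection()] whose set names are cell-type
#'   labels of `sc`.
#' @return Tibble (`cell_type`, `specificity`, `n_genes_used`).
#' @export
marker_specificity <- function(sc, markers) {
  stopifnot(inherits(sc, "sc_dataset"), inherits(markers, "marker_set_collection"))
  types <- unique(sc$cells$cell_type)
  if (length(types) < 2) abort("Need at least 2 annotated cell types.",
                               class = "lumi_validation_error")
  if (is.null(sc$normalized)) sc <- normalize_per_cell(sc)
  mat <- sc$normalized
  # mean normalized expression per (type, gene)
  type_means <- do.call(rbind, lapply(types, function(tp) {
    Matrix::colMeans(mat[sc$cells$cell_type == tp, , drop = FALSE])
  }))
  rownames(type_means) <- types
  rows <- list(); skipped <- character(0)
  for (tp in names(markers)) {
    if (!tp %in% types) {
      skipped <- c(skipped, tp)
      next
    }
    found <- intersect(markers[[tp]], colnames(type_means))
    if (!length(found)) {
      skipped <- c(skipped, tp)
      next
    }
    denom <- colSums(type_means[, found, drop = FALSE])
    spec <- ifelse(denom > 0, type_means[tp, found] / denom, 0)
    rows[[tp]] <- tibble(cell_type = tp, specificity = mean(spec),
                         n_genes_used = length(found))
  }
  if (length(skipped)) {
    warn(paste0("Marker set(s) skipped (type absent or no measured genes): ",
                paste(skipped, collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}
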