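#' Per-cell depth normalization
#'
#' Scales each cell's molecule counts so its total equals `target`
#' (default 10,000 molecules per cell). Cells with zero total molecules
#' must be removed first (see [remove_empty_cells()]); one reaching this
#' operation is an error.
#'
#' @param sc An [sc_dataset()].
#' @param target Positive per-cell total after normalization.
#' @return The dataset with a real-valued `normalized` matrix added.
#' @export
normalize_per_cell <- function(sc, target = 10000) {
  stopifnot(inherits(sc, "sc_dataset"), target > 0)
  tot <- Matrix::rowSums(sc$counts)
  if (any(tot == 0)) {
    abort("Cells with zero total molecules cannot be normalized; remove them first.",
          class = "lumi_validation_error")
  }
  sc$normalized <- sc$counts * (target / tot)
  sc$normalization_target <- target
  sc
}

#' Positive-cell rate per 1000 analysed cells
#'
#' The number of cells with at least one raw molecule of the gene, per 1000
#' cells analysed, within each stratum. Positivity uses raw counts
#' (molecule counts are integers), not normalized values.
#'
#' @param sc An [sc_dataset()].
#' @param gene Gene id.
#' @param stratify_by Annotation columns to stratify on (any of
#'   `"cell_type"`, `"group"`, `"sample_id"`).
#' @return Tibble with the strata, `n_cells`, `n_positive`,
#'   `rate_per_1000` (always in `[0, 1000]`).
#' @export
positive_cells_per_1000 <- function(sc, gene, stratify_by = c("cell_type", "group")) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (!gene %in% colnames(sc$counts)) {
    abort(paste0("Gene not measured: ", gene), class = "lumi_validation_error")
  }
  stratify_by <- match.arg(stratify_by, c("cell_type", "group", "sample_id"),
                           several.ok = TRUE)
  df <- sc$cells[stratify_by]
  df$positive <- as.numeric(sc$counts[, gene]) > 0
  df %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(stratify_by))) %>%
    dplyr::summarise(n_cells = dplyr::n(), n_positive = sum(.data$positive),
                     .groups = "drop") %>%
    dplyr::mutate(gene_id = gene,
                  rate_per_1000 = .data$n_positive / .data$n_cells * 1000)
}

#' Absolute cell-type numbers per lung
#'
#' Scales the analysed-cell proportions of each sample by that sample's
#' haemocytometer lavage total: `cells_per_lung = lavage_total x (cells of
#' type / cells analysed)`. Summing over types recovers the lavage total.
#' Samples without a lavage total are skipped with a warning.
#'
#' @param sc An [sc_dataset()].
#' @return Tibble (`sample_id`, `group`, `cell_type`, `n_analysed`,
#'   `n_of_type`, `cells_per_lung`), including zero rows for types absent
#'   from a sample.
#' @export
cells_per_lung <- function(sc) {
  stopifnot(inherits(sc, "sc_dataset"))
  totals <- stats::setNames(sc$sample_totals$total_lavage_cells_per_lung,
                            sc$sample_totals$sample_id)
  samples <- unique(sc$cells$sample_id)
  missing <- samples[!samples %in% names(totals) | is.na(totals[samples])]
  if (length(missing)) {
    warn(paste0("No lavage total for sample(s): ", paste(missing, collapse = ", "),
                "; skipped."))
    samples <- setdiff(samples, missing)
  }
  grp <- dplyr::distinct(sc$cells, .data$sample_id, .data$group)
  counts <- sc$cells %>%
    dplyr::filter(.data$sample_id %in% samples) %>%
    dplyr::count(.data$sample_id, .data$cell_type, name = "n_of_type") %>%
    tidyr::complete(sample_id = samples,
                    cell_type = sc$cell_type_levels,
                    fill = list(n_of_type = 0L))
  counts %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::mutate(n_analysed = sum(.data$n_of_type)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(cells_per_lung = unname(totals[.data$sample_id]) *
                    .data$n_of_type / .data$n_analysed) %>%
    dplyr::left_join(grp, by = "sample_id") %>%
    dplyr::select("sample_id", "group", "cell_type", "n_analysed",
                  "n_of_type", "cells_per_lung")
}

#' Total mRNA molecules of a gene per lung, by cell type
#'
#' Mean per-cell normalized expression of the gene within each
#' (sample, cell type), scaled by the absolute cells-per-lung estimate.
#' With `exclude_zero_cells = TRUE` the per-cell mean is taken over
#' expressing cells only (the display convention for per-cell expression);
#' the default includes all cells, which is the convention consistent with
#' a total.
#'
#' @param sc A normalized [sc_dataset()] (see [normalize_per_cell()]).
#' @param gene Gene id.
#' @param exclude_zero_cells Drop zero-count cells from the per-cell mean.
#' @return Tibble (`sample_id`, `group`, `cell_type`, `mean_per_cell`,
#'   `cells_per_lung`, `total_per_lung`).
#' @export
total_mrna_per_lung <- function(sc, gene, exclude_zero_cells = FALSE) {
  stopifnot(inherits(sc, "sc_dataset"))
  if (is.null(sc$normalized)) {
    abort("Normalize per cell first (normalize_per_cell()).", class = "lumi_validation_error")
  }
  if (!gene %in% colnames(sc$normalized)) {
    abort(paste0("Gene not measured: ", gene), class = "lumi_validation_error")
  }
  per_lung <- cells_per_lung(sc)
  df <- sc$cells[c("sample_id", "cell_type")]
  df$value <- as.numeric(sc$normalized[, gene])
  if (exclude_zero_cells) df <- df[df$value > 0, ]
  means <- df %>%
    dplyr::group_by(.data$sample_id, .data$cell_type) %>%
    dplyr::summarise(mean_per_cell = mean(.data$value), .groups = "drop")
  per_lung %>%
    dplyr::left_join(means, by = c("sample_id", "cell_type")) %>%
    dplyr::mutate(mean_per_cell = dplyr::coalesce(.data$mean_per_cell, 0),
                  gene_id = gene,
                  total_per_lung = .data$mean_per_cell * .data$cells_per_lung) %>%
    dplyr::select("sample_id", "group", "cell_type", "gene_id",
                  "mean_per_cell", "cells_per_lung", "total_per_lung")
}

#' Unpaired two-group comparison (Student t test)
#'
#' Two-sample t test, equal-variance (Student) by default, Welch optional;
#' two-sided. Identical constant groups return t = 0, p = 1 rather than an
#' error.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @return One-row tibble: `t_statistic`, `p_value`, `mean_a`, `sem_a`,
#'   `mean_b`, `sem_b`, `df`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("Each group needs at least 2 values.", class = "lumi_validation_error")
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  base <- tibble(mean_a = mean(values_a), sem_a = sem(values_a),
                 mean_b = mean(values_b), sem_b = sem(values_b))
  if (stats::sd(c(values_a, values_b)) == 0) {
    return(dplyr::bind_cols(tibble(t_statistic = 0, p_value = 1,
                                   df = length(values_a) + length(values_b) - 2), base))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  dplyr::bind_cols(tibble(t_statistic = unname(ht$statistic),
                          p_value = ht$p.value, df = unname(ht$parameter)), base)
}
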