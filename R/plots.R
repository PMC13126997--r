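#' Volcano plot of a contrast
#'
#' log2 fold change against -log10(q), with DEGs at the given thresholds
#' highlighted by direction.
#'
#' @param object A `contrast_table`.
#' @param fc_threshold,q_threshold Thresholds drawn and used to colour DEGs.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contrast_table <- function(object, fc_threshold = 2, q_threshold = 0.05, ...) {
  df <- as_tibble(object)
  df$status <- dplyr::case_when(
    abs(df$log2_fc) >= log2(fc_threshold) & df$q_value < q_threshold & df$log2_fc > 0 ~ "up",
    abs(df$log2_fc) >= log2(fc_threshold) & df$q_value < q_threshold ~ "down",
    TRUE ~ "ns")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(fc_threshold), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2c6fbb", ns = "grey70")) +
    ggplot2::labs(title = attr(object, "contrast"), x = "log2 fold change",
                  y = "-log10 FDR q", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of cell-type interpolation scores
#'
#' Mean DES per cell type with SEM error bars, the bulk interpolation
#' readout of relative cell-type abundance change.
#'
#' @param object A `cell_type_scores` table ([interpolate_cell_types()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cell_type_scores <- function(object, ...) {
  df <- as_tibble(object)
  df$cell_type <- stats::reorder(df$cell_type, df$mean_des)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_type, y = .data$mean_des)) +
    ggplot2::geom_col(fill = "#4c8f6e") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_des - .data$sem_des,
                                        ymax = .data$mean_des + .data$sem_des),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(title = attr(object, "contrast"),
                  x = NULL, y = "mean DES (± SEM) over marker genes") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of the compartment delta-DES sort
#'
#' Genes ranked by the LAC - TISS difference in DES; lumen-dominated
#' responders sit on the left.
#'
#' @param delta A [delta_des()] table.
#' @param n_label Label the top genes by delta.
#' @return A ggplot.
#' @export
plot_delta_des <- function(delta, n_label = 10) {
  df <- as_tibble(delta)
  df$rank <- seq_len(nrow(df))
  top <- utils::head(df, n_label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$delta)) +
    ggplot2::geom_col(width = 1, fill = "grey40") +
    ggplot2::geom_text(data = top, ggplot2::aes(label = .data$gene_id),
                       angle = 90, hjust = -0.1, size = 2.5) +
    ggplot2::labs(x = "gene rank", y = expression(Delta * "DES (LAC - TISS)")) +
    ggplot2::theme_minimal()
}
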