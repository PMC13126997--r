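#' Map a ligand-receptor table onto orthologous symbols
#'
#' Substitutes each gene symbol by its ortholog (e.g. human database symbol
#' to murine symbol). Pairs with both partners mappable are emitted with
#' `species_source = "ortholog-mapped"`; pairs with any unmappable partner
#' are dropped and counted. A source symbol mapping to more than one target
#' is an error naming the symbol.
#'
#' @param pairs An [lr_pair_table()].
#' @param mapping Tibble with columns `source`, `target` (see
#'   [read_ortholog_map()]).
#' @return An [lr_pair_table()] of the mapped pairs; attribute `n_dropped`
#'   counts dropped pairs.
#' @export
map_orthologs <- function(pairs, mapping) {
  stopifnot(inherits(pairs, "lr_pair_table"))
  mapping <- as_tibble(mapping)
  dup <- unique(mapping$source[duplicated(mapping$source)])
  if (length(dup)) {
    abort(paste0("One-to-many ortholog mapping for symbol(s): ",
                 paste(dup, collapse = ", ")), class = "lumi_validation_error")
  }
  lut <- stats::setNames(mapping$target, mapping$source)
  lig <- unname(lut[pairs$ligand]); rec <- unname(lut[pairs$receptor])
  ok <- !is.na(lig) & !is.na(rec)
  n_dropped <- sum(!ok)
  if (n_dropped) {
    inform(paste0(n_dropped, " pair(s) dropped: partner not in the ortholog map."))
  }
  out <- tibble(pair_id = pairs$pair_id[ok], ligand = lig[ok], receptor = rec[ok],
                species_source = "ortholog-mapped")
  res <- lr_pair_table(out)
  attr(res, "n_dropped") <- n_dropped
  res
}

lr_partner_cols <- function(contrast, genes, prefix) {
  idx <- match(genes, contrast$gene_id)
  out <- tibble(log2_fc = contrast$log2_fc[idx],
                q_value = contrast$q_value[idx],
                des = contrast$des[idx])
  names(out) <- paste0(prefix, "_", names(out))
  out
}

passes_thresholds <- function(log2_fc, q_value, fc_threshold, q_threshold,
                              direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  mag <- switch(direction,
                any = abs(log2_fc) >= log2(fc_threshold),
                up = log2_fc >= log2(fc_threshold),
                down = -log2_fc >= log2(fc_threshold))
  !is.na(log2_fc) & !is.na(q_value) & mag & q_value < q_threshold
}

#' Ligand-receptor co-expression screen within one compartment
#'
#' A pair is retained iff BOTH partners are differentially expressed in the
#' same contrast at the given thresholds (default 1.25-fold, q < 0.05).
#' Direction-agnostic by default (both increased and decreased pairs are
#' reported); set `direction = "up"` to require co-upregulation. Pairs with
#' a partner absent from the contrast are skipped and counted. Output is
#' sorted by the mean |DES| of the two partners, descending (ties broken by
#' pair id).
#'
#' @param contrast A `contrast_table`.
#' @param pairs An [lr_pair_table()].
#' @param fc_threshold,q_threshold DE thresholds.
#' @param direction `"any"` (default), `"up"` or `"down"` for both partners.
#' @return Tibble: `pair_id`, `ligand`, `receptor`, per-partner `log2_fc`,
#'   `q_value`, `des`, and `mean_abs_des`; attribute `n_skipped`.
#' @export
screen_pairs_within <- function(contrast, pairs, fc_threshold = 1.25,
                                q_threshold = 0.05, direction = "any") {
  stopifnot(inherits(pairs, "lr_pair_table"), fc_threshold > 1)
  measured <- pairs$ligand %in% contrast$gene_id & pairs$receptor %in% contrast$gene_id
  n_skipped <- sum(!measured)
  if (n_skipped) inform(paste0(n_skipped, " pair(s) skipped: partner not measured."))
  p <- pairs[measured, ]
  lig <- lr_partner_cols(contrast, p$ligand, "ligand")
  rec <- lr_partner_cols(contrast, p$receptor, "receptor")
  keep <- passes_thresholds(lig$ligand_log2_fc, lig$ligand_q_value,
                            fc_threshold, q_threshold, direction) &
    passes_thresholds(rec$receptor_log2_fc, rec$receptor_q_value,
                      fc_threshold, q_threshold, direction)
  out <- dplyr::bind_cols(p[keep, c("pair_id", "ligand", "receptor")],
                          lig[keep, ], rec[keep, ])
  out$mean_abs_des <- (abs(out$ligand_des) + abs(out$receptor_des)) / 2
  out <- out[order(-out$mean_abs_des, out$pair_id), ]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Directional ligand-receptor screen across compartments
#'
#' Tests cross-compartment signalling directionality: a pair is retained
#' iff the ligand passes the thresholds in `ligand_contrast` (one
#' compartment) AND the receptor passes in `receptor_contrast` (the other),
#' both upregulated by default — the recruitment reading of a
#' lumen-to-tissue (or tissue-to-lumen) axis. Swapping the contrasts
#' reverses the direction label.
#'
#' @param ligand_contrast,receptor_contrast `contrast_table`s for the two
#'   compartments of one comparison.
#' @param pairs An [lr_pair_table()].
#' @param fc_threshold,q_threshold DE thresholds.
#' @param direction Required direction in each compartment (default "up").
#' @return As [screen_pairs_within()], plus a `direction_label` column
#'   `"<ligand compartment>-><receptor compartment>"` built from the
#'   contrasts' compartment attributes.
#' @export
screen_pairs_cross <- function(ligand_contrast, receptor_contrast, pairs,
                               fc_threshold = 1.25, q_threshold = 0.05,
                               direction = "up") {
  stopifnot(inherits(pairs, "lr_pair_table"))
  measured <- pairs$ligand %in% ligand_contrast$gene_id &
    pairs$receptor %in% receptor_contrast$gene_id
  n_skipped <- sum(!measured)
  if (n_skipped) inform(paste0(n_skipped, " pair(s) skipped: partner not measured."))
  p <- pairs[measured, ]
  lig <- lr_partner_cols(ligand_contrast, p$ligand, "ligand")
  rec <- lr_partner_cols(receptor_contrast, p$receptor, "receptor")
  keep <- passes_thresholds(lig$ligand_log2_fc, lig$ligand_q_value,
                            fc_threshold, q_threshold, direction) &
    passes_thresholds(rec$receptor_log2_fc, rec$receptor_q_value,
                      fc_threshold, q_threshold, direction)
  out <- dplyr::bind_cols(p[keep, c("pair_id", "ligand", "receptor")],
                          lig[keep, ], rec[keep, ])
  out$mean_abs_des <- (abs(out$ligand_des) + abs(out$receptor_des)) / 2
  out$direction_label <- paste0(attr(ligand_contrast, "compartment") %||% "ligand",
                                "->",
                                attr(receptor_contrast, "compartment") %||% "receptor")
  out <- out[order(-out$mean_abs_des, out$pair_id), ]
  attr(out, "n_skipped") <- n_skipped
  out
}
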