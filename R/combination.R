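#' Genes uniquely regulated by the combination exposure
#'
#' The Venn construction for combination-specific genes: the sign-consistent
#' intersection of two DEG sets from contrasts that share the combination
#' arm (combination vs particle alone, combination vs allergen alone). A
#' gene is kept only if it is a DEG in both contrasts with the same
#' direction; direction conflicts are excluded and reported. Both up- and
#' down-regulated genes are retained. Symmetric in its two arguments.
#'
#' @param deg_comb_vs_p,deg_comb_vs_a [call_degs()] results for the two
#'   combination-vs-single contrasts.
#' @return Tibble (`gene_id`, `direction`), sorted by gene id; attribute
#'   `conflicts` lists sign-conflicting genes.
#' @export
combination_unique_genes <- function(deg_comb_vs_p, deg_comb_vs_a) {
  a <- stats::setNames(deg_comb_vs_p$direction, deg_comb_vs_p$gene_id)
  b <- stats::setNames(deg_comb_vs_a$direction, deg_comb_vs_a$gene_id)
  common <- intersect(names(a), names(b))
  agree <- common[a[common] == b[common]]
  conflict <- setdiff(common, agree)
  if (length(conflict)) {
    inform(paste0(length(conflict), " gene(s) excluded for direction conflict: ",
                  paste(utils::head(conflict, 5), collapse = ", "),
                  if (length(conflict) > 5) ", ..." else ""))
  }
  agree <- sort(agree)
  structure(tibble(gene_id = agree, direction = unname(a[agree])),
            conflicts = conflict)
}

#' Genes enhanced beyond either single treatment
#'
#' A gene qualifies iff it is significant at the given thresholds in BOTH
#' combination-vs-single contrasts with the same direction — change beyond
#' the level reached by either treatment alone. The per-gene minimum |DES|
#' across the two contrasts is reported as the conservative effect summary.
#'
#' @param contrast_comb_vs_a,contrast_comb_vs_p `contrast_table`s with the
#'   combination as the alternative arm.
#' @param fc_threshold,q_threshold DEG thresholds (defaults 2, 0.05).
#' @return Tibble (`gene_id`, `direction`, `min_abs_des`), sorted by
#'   `min_abs_des` descending then gene id.
#' @export
enhanced_beyond_single <- function(contrast_comb_vs_a, contrast_comb_vs_p,
                                   fc_threshold = 2, q_threshold = 0.05) {
  d1 <- call_degs(contrast_comb_vs_a, fc_threshold, q_threshold)
  d2 <- call_degs(contrast_comb_vs_p, fc_threshold, q_threshold)
  joint <- dplyr::inner_join(
    dplyr::select(as_tibble(d1), "gene_id", dir1 = "direction", des1 = "des"),
    dplyr::select(as_tibble(d2), "gene_id", dir2 = "direction", des2 = "des"),
    by = "gene_id")
  joint <- joint[joint$dir1 == joint$dir2, ]
  out <- tibble(gene_id = joint$gene_id, direction = joint$dir1,
                min_abs_des = pmin(abs(joint$des1), abs(joint$des2)))
  out[order(-out$min_abs_des, out$gene_id), ]
}

#' Common response genes across two particle types
#'
#' The sign-consistent intersection of two particle-alone DEG sets (called
#' at matching thresholds, conventionally 1.5-fold / q < 0.05), with each
#' contrast's DES paired for display; sorted by the mean of the two DES
#' values, descending.
#'
#' @param deg_particle1,deg_particle2 [call_degs()] results for the two
#'   particle-vs-control contrasts.
#' @param contrast1,contrast2 The contrasts the DEG sets derive from.
#' @return Tibble (`gene_id`, `direction`, `des_1`, `des_2`, `mean_des`).
#' @export
cross_particle_common <- function(deg_particle1, deg_particle2, contrast1, contrast2) {
  t1 <- attr(deg_particle1, "fc_threshold"); t2 <- attr(deg_particle2, "fc_threshold")
  q1 <- attr(deg_particle1, "q_threshold"); q2 <- attr(deg_particle2, "q_threshold")
  if (!is.null(t1) && !is.null(t2) && (!isTRUE(all.equal(t1, t2)) || !isTRUE(all.equal(q1, q2)))) {
    warn("DEG sets were called at different thresholds.")
  }
  shared <- combination_unique_genes(deg_particle1, deg_particle2)
  if (nrow(shared) == 0) {
    return(tibble(gene_id = character(0), direction = numeric(0),
                  des_1 = numeric(0), des_2 = numeric(0), mean_des = numeric(0)))
  }
  des1 <- stats::setNames(contrast1$des, contrast1$gene_id)[shared$gene_id]
  des2 <- stats::setNames(contrast2$des, contrast2$gene_id)[shared$gene_id]
  out <- tibble(gene_id = shared$gene_id, direction = shared$direction,
                des_1 = unname(des1), des_2 = unname(des2),
                mean_des = (unname(des1) + unname(des2)) / 2)
  out[order(-out$mean_des, out$gene_id), ]
}
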