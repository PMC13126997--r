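#' Default cell types of the synthetic airway study
#'
#' Ten luminal immune cell types: resident alveolar macrophages (AM),
#' alternatively activated macrophages (AAM), recruited monocyte-derived
#' macrophages (RM.Mo), eosinophils, neutrophils, T cells, B cells, mast
#' cells, dendritic cells and NK cells.
#'
#' @export
default_cell_types <- c("AM", "AAM", "RM.Mo", "Eos", "Neut",
                        "Tcell", "Bcell", "Mast", "DC", "NK")

#' Default cell-type composition of the synthetic study
#'
#' Per-(group, compartment) cell-type fractions emulating a two-particle
#' co-exposure design. In the airway lumen (LAC) the alternatively activated
#' macrophage fraction rises 0.02 (CTRL) -> 0.05 (DEP) -> 0.15 (HDM) -> 0.35
#' (D+H); eosinophils, mast cells, B cells and recruited monocytes expand
#' under allergen while resident alveolar macrophages and lymphocytes are
#' proportionally displaced, so every cell type follows a distinct
#' trajectory. Tissue (TISS) composition is held constant across groups,
#' reflecting a lumen-dominated response. CEP/CH arms (a second particle)
#' copy the DEP/DH shifts.
#'
#' @param include_cep Add CEP and CH arms mirroring DEP and DH.
#' @param null_combination Make DEP, HDM and the combination arm(s)
#'   identical to CTRL (a no-treatment-effect null design).
#' @return A tibble with columns `group`, `compartment`, `cell_type`,
#'   `fraction`; fractions sum to 1 within each (group, compartment).
#' @export
default_composition <- function(include_cep = FALSE, null_combination = FALSE) {
  lac <- rbind(
    CTRL = c(0.60, 0.02, 0.05, 0.020, 0.03, 0.12, 0.06, 0.005, 0.045, 0.050),
    DEP  = c(0.53, 0.05, 0.08, 0.020, 0.06, 0.11, 0.06, 0.005, 0.040, 0.045),
    HDM  = c(0.30, 0.15, 0.10, 0.180, 0.04, 0.10, 0.08, 0.010, 0.030, 0.010),
    DH   = c(0.12, 0.35, 0.13, 0.195, 0.03, 0.07, 0.05, 0.025, 0.020, 0.010))
  tiss <- c(0.10, 0.02, 0.08, 0.02, 0.05, 0.25, 0.18, 0.02, 0.08, 0.20)
  colnames(lac) <- default_cell_types
  if (null_combination) for (g in c("DEP", "HDM", "DH")) lac[g, ] <- lac["CTRL", ]
  groups <- rownames(lac)
  rows <- list()
  for (g in groups) {
    rows[[length(rows) + 1]] <- tibble(group = g, compartment = "LAC",
                                       cell_type = default_cell_types,
                                       fraction = unname(lac[g, ]))
    rows[[length(rows) + 1]] <- tibble(group = g, compartment = "TISS",
                                       cell_type = default_cell_types,
                                       fraction = tiss)
  }
  comp <- dplyr::bind_rows(rows)
  if (include_cep) {
    extra <- dplyr::filter(comp, .data$group %in% c("DEP", "DH"))
    extra$group <- ifelse(extra$group == "DEP", "CEP", "CH")
    comp <- dplyr::bind_rows(comp, extra)
  }
  comp
}

derive_seed <- function(seed, salt) {
  (as.integer(seed) %% 65011 + 1L) * 31013L %% 2147483647L +
    sum(utf8ToInt(salt)) %% 100000L
}

#' Generate exclusive cell-type signature profiles
#'
#' Builds per-cell-type expression profiles over a synthetic gene universe:
#' each type receives `markers_per_type` exclusive marker genes (high weight
#' in the owning type, exactly zero elsewhere) and all types share a common
#' background. Each type's profile is normalized to sum to 1, so a
#' composition-weighted mixture of profiles is itself a probability
#' distribution over genes. Gene names and lengths are deterministic given
#' the seed.
#'
#' @param n_types,markers_per_type,n_background_genes Positive integers.
#' @param seed Integer seed (controls gene lengths only; the profile
#'   structure is deterministic).
#' @param type_names Optional cell-type names (defaults to
#'   [default_cell_types] when `n_types == 10`, else `CT01`...).
#' @param marker_weight,background_weight Relative within-type expression
#'   of a marker vs a background gene (default 25:1).
#' @param gene_cap Guard against runaway universe sizes.
#' @return A partial `synthetic_truth` list: `signature_matrix` (genes x
#'   types, columns sum to 1), `marker_map` (type -> marker gene ids),
#'   `gene_lengths`, `seed`.
#' @export
generate_signatures <- function(n_types = 10, markers_per_type = 20,
                                n_background_genes = 2000, seed = 1,
                                type_names = NULL, marker_weight = 25,
                                background_weight = 1, gene_cap = 50000) {
  stopifnot(n_types > 0, markers_per_type > 0, n_background_genes > 0)
  if (n_types * markers_per_type > gene_cap) {
    abort("Requested marker genes exceed the configured gene cap.",
          class = "lumi_validation_error")
  }
  if (is.null(type_names)) {
    type_names <- if (n_types == 10) default_cell_types else sprintf("CT%02d", seq_len(n_types))
  }
  stopifnot(length(type_names) == n_types)
  marker_map <- lapply(type_names, function(tp) {
    sprintf("Mk.%s.%02d", tp, seq_len(markers_per_type))
  })
  names(marker_map) <- type_names
  bg_genes <- sprintf("Bg%04d", seq_len(n_background_genes))
  genes <- c(unlist(marker_map, use.names = FALSE), bg_genes)
  sig <- matrix(0, nrow = length(genes), ncol = n_types,
                dimnames = list(genes, type_names))
  sig[bg_genes, ] <- background_weight
  for (tp in type_names) sig[marker_map[[tp]], tp] <- marker_weight
  sig <- sweep(sig, 2, colSums(sig), "/")
  withr::local_seed(derive_seed(seed, "lengths"))
  lengths_bp <- stats::setNames(sample(500:5000, length(genes), replace = TRUE), genes)
  list(signature_matrix = sig, marker_map = marker_map,
       gene_lengths = lengths_bp, background_genes = bg_genes, seed = seed)
}

#' Assemble a full synthetic ground truth
#'
#' @param signatures Output of [generate_signatures()].
#' @param composition Tibble (`group`, `compartment`, `cell_type`,
#'   `fraction`); fractions must sum to 1 (within 1e-9) per
#'   (group, compartment) and cover every signature cell type.
#' @param synergy_genes Genes whose expression is multiplied by
#'   `synergy_multiplier` only in the combination arm(s) (`DH`, `CH`);
#'   single-particle and single-allergen arms get multiplier 1.
#' @param synergy_multiplier Fold multiplier applied in combination arms
#'   (default 4).
#' @param dispersion Negative-binomial dispersion alpha (variance =
#'   mu + alpha mu^2); a scalar (constant per gene) or per-gene vector.
#' @param library_size_range Min/max bulk library size (counts per sample).
#' @param de_effects Optional genes x groups matrix of extra fold
#'   multipliers (natural scale, default none).
#' @param seed Integer seed recorded with the truth.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(signatures, composition, synergy_genes = character(0),
                            synergy_multiplier = 4, dispersion = 0.1,
                            library_size_range = c(1e6, 3e6),
                            de_effects = NULL, seed = 1) {
  sig <- signatures$signature_matrix
  composition <- as_tibble(composition)
  sums <- composition %>%
    dplyr::group_by(.data$group, .data$compartment) %>%
    dplyr::summarise(s = sum(.data$fraction), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort("Composition fractions must sum to 1 within each (group, compartment).",
          class = "lumi_validation_error")
  }
  if (any(composition$fraction < 0)) {
    abort("Composition fractions must be non-negative.", class = "lumi_validation_error")
  }
  missing_types <- setdiff(unique(composition$cell_type), colnames(sig))
  if (length(missing_types)) {
    abort(paste0("Composition references unknown cell type(s): ",
                 paste(missing_types, collapse = ", ")), class = "lumi_validation_error")
  }
  if (length(synergy_genes) && !all(synergy_genes %in% rownames(sig))) {
    abort("Synergy genes must belong to the gene universe.", class = "lumi_validation_error")
  }
  if (any(dispersion <= 0)) abort("Dispersion must be positive.", class = "lumi_validation_error")
  stopifnot(length(library_size_range) == 2, all(library_size_range > 0),
            library_size_range[1] <= library_size_range[2])
  structure(list(signature_matrix = sig, marker_map = signatures$marker_map,
                 gene_lengths = signatures$gene_lengths,
                 background_genes = signatures$background_genes,
                 composition = composition, synergy_genes = synergy_genes,
                 synergy_multiplier = synergy_multiplier,
                 dispersion = dispersion, library_size_range = library_size_range,
                 de_effects = de_effects, seed = seed),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$signature_matrix), " genes, ",
      ncol(x$signature_matrix), " cell types, ",
      length(x$synergy_genes), " synergy genes (x", x$synergy_multiplier, ")\n", sep = "")
  invisible(x)
}

combination_groups <- c("DH", "CH")

#' Per-gene expected relative expression for one study condition
#'
#' The composition-weighted mixture of signature profiles, times any
#' synergy/extra effect multipliers for the group. Multiplied by a library
#' size this is the NB mean used by [generate_bulk()].
#'
#' @param truth A [synthetic_truth()].
#' @param group,compartment Condition.
#' @return Named numeric vector over genes.
#' @export
expected_relative_expression <- function(truth, group, compartment) {
  comp <- dplyr::filter(truth$composition,
                        .data$group == !!group, .data$compartment == !!compartment)
  if (nrow(comp) == 0) {
    abort(paste0("No composition defined for (", group, ", ", compartment, ")."),
          class = "lumi_validation_error")
  }
  pi_vec <- stats::setNames(comp$fraction, comp$cell_type)[colnames(truth$signature_matrix)]
  p <- as.numeric(truth$signature_matrix %*% pi_vec)
  names(p) <- rownames(truth$signature_matrix)
  if (length(truth$synergy_genes) && group %in% combination_groups) {
    p[truth$synergy_genes] <- p[truth$synergy_genes] * truth$synergy_multiplier
  }
  if (!is.null(truth$de_effects) && group %in% colnames(truth$de_effects)) {
    p <- p * truth$de_effects[names(p), group]
  }
  p
}

#' Simulate a bulk expression study from a synthetic truth
#'
#' Counts are negative-binomial: count_gs ~ NB(mean = L_s * mixture
#' expression, dispersion alpha) with variance mu + alpha mu^2; the
#' per-sample library size L_s is uniform over `library_size_range`.
#' Synergy genes are multiplied only in the combination arm(s). R's default
#' Mersenne-Twister RNG is used throughout; a fixed seed reproduces the
#' study exactly.
#'
#' @param truth A [synthetic_truth()].
#' @param n_replicates Replicates per (group, compartment).
#' @param seed Integer seed.
#' @return An [expression_matrix()] covering every (group, compartment) in
#'   the truth's composition.
#' @export
generate_bulk <- function(truth, n_replicates = 5, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"), n_replicates >= 1)
  conds <- dplyr::distinct(truth$composition, .data$group, .data$compartment)
  conds <- conds[order(match(conds$group, group_levels), conds$compartment), ]
  genes <- rownames(truth$signature_matrix)
  alpha <- rep_len(truth$dispersion, length(genes))
  withr::local_seed(derive_seed(seed, "bulk"))
  cols <- list(); meta <- list()
  for (i in seq_len(nrow(conds))) {
    g <- conds$group[i]; cp <- conds$compartment[i]
    p <- expected_relative_expression(truth, g, cp)
    for (r in seq_len(n_replicates)) {
      L <- round(stats::runif(1, truth$library_size_range[1], truth$library_size_range[2]))
      mu <- L * p
      y <- stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
      sid <- paste(g, cp, r, sep = "_")
      cols[[sid]] <- y
      meta[[sid]] <- tibble(sample_id = sid, group = g, compartment = cp, replicate = r)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- genes
  expression_matrix(counts, truth$gene_lengths, dplyr::bind_rows(meta))
}

#' Simulate a single-cell molecule-count dataset
#'
#' For each sample, cell types are drawn from the sample's (group,
#' compartment) composition; each cell's gene counts are a single
#' multinomial draw of `molecules_per_cell` molecules over the owning
#' type's signature profile (times any group effect multipliers). The true
#' cell type is stored as the annotation. Per-sample total lavage cell
#' counts are drawn uniformly from `lavage_range`.
#'
#' @param truth A [synthetic_truth()].
#' @param cells_per_sample,molecules_per_cell Positive integers.
#' @param seed Integer seed.
#' @param design Tibble (`sample_id`, `group`) of samples to simulate;
#'   default four replicates each of HDM and DH, the study's single-cell
#'   arms.
#' @param compartment Compartment whose composition is used (default LAC:
#'   single-cell profiling is of lavage cells).
#' @param lavage_range Min/max haemocytometer lavage total per lung.
#' @return An [sc_dataset()].
#' @export
generate_sc <- function(truth, cells_per_sample = 1000, molecules_per_cell = 5000,
                        seed = truth$seed, design = NULL, compartment = "LAC",
                        lavage_range = c(3e5, 8e5)) {
  stopifnot(inherits(truth, "synthetic_truth"),
            cells_per_sample > 0, molecules_per_cell > 0)
  if (is.null(design)) {
    design <- tibble(sample_id = c(paste0("HDM_sc", 1:4), paste0("DH_sc", 1:4)),
                     group = rep(c("HDM", "DH"), each = 4))
  }
  genes <- rownames(truth$signature_matrix)
  types <- colnames(truth$signature_matrix)
  withr::local_seed(derive_seed(seed, "sc"))
  blocks <- list(); ann <- list()
  for (i in seq_len(nrow(design))) {
    sid <- design$sample_id[i]; g <- design$group[i]
    comp <- dplyr::filter(truth$composition,
                          .data$group == !!g, .data$compartment == !!compartment)
    if (nrow(comp) == 0) {
      abort(paste0("No composition defined for (", g, ", ", compartment, ")."),
            class = "lumi_validation_error")
    }
    pi_vec <- stats::setNames(comp$fraction, comp$cell_type)[types]
    cell_types <- sample(types, cells_per_sample, replace = TRUE, prob = pi_vec)
    eff <- rep(1, length(genes)); names(eff) <- genes
    if (length(truth$synergy_genes) && g %in% combination_groups) {
      eff[truth$synergy_genes] <- truth$synergy_multiplier
    }
    m <- matrix(0L, nrow = cells_per_sample, ncol = length(genes))
    for (tp in unique(cell_types)) {
      idx <- which(cell_types == tp)
      prob <- truth$signature_matrix[, tp] * eff
      draws <- stats::rmultinom(length(idx), molecules_per_cell, prob)
      m[idx, ] <- t(draws)
    }
    blocks[[sid]] <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    ann[[sid]] <- tibble(cell_id = sprintf("%s_c%04d", sid, seq_len(cells_per_sample)),
                         cell_type = cell_types, sample_id = sid, group = g)
  }
  counts <- do.call(rbind, blocks)
  cells <- dplyr::bind_rows(ann)
  colnames(counts) <- genes
  totals <- tibble(sample_id = design$sample_id,
                   total_lavage_cells_per_lung =
                     round(stats::runif(nrow(design), lavage_range[1], lavage_range[2])))
  sc_dataset(counts, cells, totals, cell_type_levels = types)
}

#' Generate a ligand-receptor pair table wired to the synthetic truth
#'
#' "True" pairs connect two synergy-responsive genes (ligand and receptor
#' both elevated only in the combination arm); "null" pairs connect inert
#' background genes. Which is which is recorded in the `is_true` attribute.
#'
#' @param truth A [synthetic_truth()].
#' @param n_true_pairs,n_null_pairs Pair counts.
#' @param seed Integer seed.
#' @return An [lr_pair_table()] with attribute `is_true` (logical per row).
#' @export
generate_lr_table <- function(truth, n_true_pairs = 5, n_null_pairs = 20,
                              seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (2 * n_true_pairs > length(truth$synergy_genes)) {
    abort("Not enough synergy genes to wire the requested true pairs.",
          class = "lumi_validation_error")
  }
  withr::local_seed(derive_seed(seed, "lr"))
  syn <- sample(truth$synergy_genes, 2 * n_true_pairs)
  inert <- setdiff(truth$background_genes, truth$synergy_genes)
  if (2 * n_null_pairs > length(inert)) {
    abort("Not enough background genes to wire the requested null pairs.",
          class = "lumi_validation_error")
  }
  bg <- sample(inert, 2 * n_null_pairs)
  tab <- lr_pair_table(tibble(
    pair_id = c(sprintf("TP%02d", seq_len(n_true_pairs)),
                sprintf("NP%02d", seq_len(n_null_pairs))),
    ligand = c(syn[seq_len(n_true_pairs)], bg[seq_len(n_null_pairs)]),
    receptor = c(syn[n_true_pairs + seq_len(n_true_pairs)],
                 bg[n_null_pairs + seq_len(n_null_pairs)]),
    species_source = "native"))
  attr(tab, "is_true") <- c(rep(TRUE, n_true_pairs), rep(FALSE, n_null_pairs))
  tab
}

#' Study configuration for the synthetic generator
#'
#' Collects every tunable of [make_study()] with the package defaults: 10
#' cell types with 20 exclusive markers each over 2000 background genes,
#' 5 replicates per (group, compartment), NB dispersion 0.1, library sizes
#' 1e6-3e6, 20 synergy genes at 4x in the combination arm, 1000 cells and
#' 5000 molecules per single-cell sample, 5 true / 20 null LR pairs.
#'
#' @param ... Overrides for any default (unknown names are an error).
#' @return A named list of class `study_config`.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_types = 10, markers_per_type = 20, n_background_genes = 2000,
    n_replicates = 5, dispersion = 0.1, library_size_range = c(1e6, 3e6),
    n_synergy_genes = 20, synergy_multiplier = 4,
    include_cep = FALSE, null_combination = FALSE,
    cells_per_sample = 1000, molecules_per_cell = 5000,
    lavage_range = c(3e5, 8e5),
    n_true_pairs = 5, n_null_pairs = 20)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown study_config key(s): ", paste(unknown, collapse = ", ")),
          class = "lumi_config_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose top-level keys are [study_config()]
#'   arguments; unknown keys are rejected before any compute.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' Generate a complete, internally consistent synthetic study
#'
#' One call yields bulk counts for all arms and both compartments, a
#' single-cell dataset for the HDM and D+H arms, the true exclusive marker
#' sets, a wired ligand-receptor pair table and the generating truth —
#' all reproducible from one seed.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_study` with elements `bulk`, `sc`,
#'   `markers`, `lr_pairs`, `truth`.
#' @export
make_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  sig <- generate_signatures(config$n_types, config$markers_per_type,
                             config$n_background_genes, seed = seed)
  comp <- default_composition(include_cep = config$include_cep,
                              null_combination = config$null_combination)
  if (config$n_types != 10) {
    abort("The default composition covers the 10 default cell types; supply a custom composition via synthetic_truth() for other designs.",
          class = "lumi_config_error")
  }
  n_syn <- if (config$null_combination) 0 else config$n_synergy_genes
  withr::with_seed(derive_seed(seed, "synergy"), {
    synergy <- if (n_syn > 0) sample(sig$background_genes, n_syn) else character(0)
  })
  truth <- synthetic_truth(sig, comp, synergy_genes = synergy,
                           synergy_multiplier = config$synergy_multiplier,
                           dispersion = config$dispersion,
                           library_size_range = config$library_size_range,
                           seed = seed)
  bulk <- generate_bulk(truth, n_replicates = config$n_replicates, seed = seed)
  sc <- generate_sc(truth, cells_per_sample = config$cells_per_sample,
                    molecules_per_cell = config$molecules_per_cell,
                    seed = seed, lavage_range = config$lavage_range)
  markers <- suppressWarnings(marker_set_collection(truth$marker_map))
  lr <- if (n_syn >= 2 * config$n_true_pairs) {
    generate_lr_table(truth, config$n_true_pairs, config$n_null_pairs, seed = seed)
  } else NULL
  structure(list(bulk = bulk, sc = sc, markers = markers, lr_pairs = lr,
                 truth = truth, config = config),
            class = "synthetic_study")
}

#' True log2 composition change between two arms
#'
#' @param truth A [synthetic_truth()].
#' @param alt,ref Treatment groups compared (alt vs ref).
#' @param compartment Compartment.
#' @return Tibble (`cell_type`, `fraction_ref`, `fraction_alt`,
#'   `log2_change`).
#' @export
composition_log2_change <- function(truth, alt = "DH", ref = "CTRL",
                                    compartment = "LAC") {
  a <- dplyr::filter(truth$composition, .data$group == alt,
                     .data$compartment == !!compartment)
  r <- dplyr::filter(truth$composition, .data$group == ref,
                     .data$compartment == !!compartment)
  out <- dplyr::inner_join(
    dplyr::select(r, "cell_type", fraction_ref = "fraction"),
    dplyr::select(a, "cell_type", fraction_alt = "fraction"),
    by = "cell_type")
  out$log2_change <- log2(out$fraction_alt / out$fraction_ref)
  out
}

#' Genes truly combination-regulated by construction
#'
#' The ground-truth answer set for combination-specific gene discovery:
#' injected synergy genes (if the synergy multiplier reaches the fold
#' threshold) plus the exclusive markers of cell types whose combination-arm
#' fraction is at least `fc_threshold`-fold above (direction +1) or below
#' (direction -1) BOTH single-treatment fractions — those markers' bulk
#' expression is genuinely enhanced (or suppressed) beyond either single
#' treatment, by construction.
#'
#' @param truth A [synthetic_truth()].
#' @param fc_threshold Fold threshold the discovery procedure uses.
#' @param comb,singles Combination arm and its two single-treatment arms.
#' @param compartment Compartment.
#' @return Tibble (`gene_id`, `direction`).
#' @export
combination_enhanced_truth <- function(truth, fc_threshold = 2, comb = "DH",
                                       singles = c("DEP", "HDM"),
                                       compartment = "LAC") {
  stopifnot(length(singles) == 2)
  out <- list()
  if (length(truth$synergy_genes) && truth$synergy_multiplier >= fc_threshold) {
    out[[1]] <- tibble(gene_id = truth$synergy_genes, direction = 1)
  }
  frac <- function(g, tp) {
    x <- dplyr::filter(truth$composition, .data$group == g,
                       .data$compartment == !!compartment,
                       .data$cell_type == tp)$fraction
    if (length(x)) x else NA_real_
  }
  for (tp in names(truth$marker_map)) {
    pc <- frac(comb, tp); p1 <- frac(singles[1], tp); p2 <- frac(singles[2], tp)
    if (anyNA(c(pc, p1, p2))) next
    up <- pc > 0 && pc >= fc_threshold * p1 && pc >= fc_threshold * p2
    down <- p1 > 0 && p2 > 0 && pc <= p1 / fc_threshold && pc <= p2 / fc_threshold
    if (up || down) {
      out[[length(out) + 1]] <- tibble(gene_id = truth$marker_map[[tp]],
                                       direction = if (up) 1 else -1)
    }
  }
  if (!length(out)) return(tibble(gene_id = character(0), direction = numeric(0)))
  dplyr::bind_rows(out)
}
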