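#' Run the full synthetic-study pipeline
#'
#' Orchestrates simulate -> differential expression -> cell-type
#' interpolation -> delta-DES -> combination set logic -> ligand-receptor
#' screen -> single-cell quantification from one configuration and seed,
#' writing every output table plus a manifest (parameters, seed, package
#' version, per-file MD5 checksums) and a plain-text log with stage timings
#' and a seed echo to `out_dir`. A stage failure aborts with the failing
#' stage named and leaves a `FAILED` marker file alongside any partial
#' outputs. Identical config and seed give byte-identical outputs.
#'
#' @param config A [study_config()] or a YAML path readable by
#'   [read_study_config()].
#' @param out_dir Output directory (created).
#' @param seed Integer seed; fanned out to stages by stable derivation.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = study_config(), out_dir, seed = 1) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- c(paste0("lumideconv ", as.character(utils::packageVersion("lumideconv"))),
                 paste0("seed: ", seed))
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage: ", name, " — ", conditionMessage(e))),
                 log_path)
      file.create(file.path(out_dir, "FAILED"))
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "lumi_pipeline_error")
    })
    log_lines <<- c(log_lines, sprintf("stage %-12s %8.2f s", name,
                                       as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  study <- stage("simulate", make_study(config, seed = seed))
  write_results_table(study$bulk$samples, file.path(out_dir, "samples.tsv"))

  contrasts <- stage("de", {
    list(
      dh_ctrl_lac = run_contrast(study$bulk, "CTRL", "DH", compartment = "LAC"),
      dh_ctrl_tiss = run_contrast(study$bulk, "CTRL", "DH", compartment = "TISS"),
      dh_dep_lac = run_contrast(study$bulk, "DEP", "DH", compartment = "LAC"),
      dh_hdm_lac = run_contrast(study$bulk, "HDM", "DH", compartment = "LAC"))
  })
  for (nm in names(contrasts)) {
    write_results_table(as_tibble(contrasts[[nm]]),
                        file.path(out_dir, paste0("contrast_", nm, ".tsv")))
  }

  celltypes <- stage("interpolate",
                     interpolate_cell_types(contrasts$dh_ctrl_lac, study$markers))
  write_results_table(as_tibble(celltypes), file.path(out_dir, "celltypes.tsv"))

  delta <- stage("deltades", delta_des(contrasts$dh_ctrl_lac, contrasts$dh_ctrl_tiss))
  write_results_table(delta, file.path(out_dir, "delta_des.tsv"))

  combo <- stage("combo", {
    d1 <- call_degs(contrasts$dh_dep_lac)
    d2 <- call_degs(contrasts$dh_hdm_lac)
    list(unique = combination_unique_genes(d1, d2),
         enhanced = enhanced_beyond_single(contrasts$dh_dep_lac, contrasts$dh_hdm_lac))
  })
  write_results_table(combo$unique, file.path(out_dir, "combo_unique.tsv"))
  write_results_table(combo$enhanced, file.path(out_dir, "combo_enhanced.tsv"))

  lr <- stage("lrscreen", {
    if (is.null(study$lr_pairs)) tibble() else
      screen_pairs_within(contrasts$dh_hdm_lac, study$lr_pairs)
  })
  write_results_table(as_tibble(lr), file.path(out_dir, "lr_within.tsv"))

  scq <- stage("scquant", {
    sc <- normalize_per_cell(remove_empty_cells(study$sc))
    goi <- utils::head(study$truth$synergy_genes, 2)
    list(cells_per_lung = cells_per_lung(sc),
         positive = if (length(goi)) dplyr::bind_rows(
           lapply(goi, function(g) positive_cells_per_1000(sc, g))) else tibble(),
         totals = if (length(goi)) dplyr::bind_rows(
           lapply(goi, function(g) total_mrna_per_lung(sc, g))) else tibble())
  })
  write_results_table(scq$cells_per_lung, file.path(out_dir, "sc_cells_per_lung.tsv"))
  write_results_table(scq$positive, file.path(out_dir, "sc_positive_per_1000.tsv"))
  write_results_table(scq$totals, file.path(out_dir, "sc_total_mrna_per_lung.tsv"))

  tables <- list.files(out_dir, pattern = "\\.tsv$")
  manifest <- list(
    package = "lumideconv",
    version = as.character(utils::packageVersion("lumideconv")),
    seed = seed,
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(out_dir, sort(tables)))))
  names(manifest$checksums) <- sort(tables)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_lines <- c(log_lines, sprintf("total %19.2f s",
                                    as.numeric(difftime(Sys.time(), t_all, units = "secs"))))
  writeLines(log_lines, log_path)
  invisible(list(study = study, contrasts = contrasts, celltypes = celltypes,
                 delta = delta, combo = combo, lr = lr, scquant = scq))
}
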