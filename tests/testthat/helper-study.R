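# Shared fixtures, generated in code and cached across test files so the
# expensive NB fits run once per session.

.lumi_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .lumi_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .lumi_cache)
  }
  get(key, envir = .lumi_cache, inherits = FALSE)
}

# Reduced-scale study for unit tests: same structure as the default design,
# fewer genes and replicates.
small_config <- function(...) {
  study_config(markers_per_type = 5, n_background_genes = 300, n_replicates = 3,
               cells_per_sample = 200, molecules_per_cell = 1000,
               library_size_range = c(2e5, 4e5), ...)
}

small_study <- function() {
  cached("small_study", suppressWarnings(make_study(small_config(), seed = 101)))
}

small_contrast <- function(ref, alt, compartment = "LAC") {
  key <- paste("ct", ref, alt, compartment, sep = "_")
  cached(key, run_contrast(small_study()$bulk, ref, alt, compartment = compartment))
}

# Full default-scale study for the recovery/acceptance tests.
default_study <- function() {
  cached("default_study", suppressWarnings(make_study(study_config(), seed = 303)))
}

default_contrast <- function(ref, alt, compartment = "LAC") {
  key <- paste("dct", ref, alt, compartment, sep = "_")
  cached(key, run_contrast(default_study()$bulk, ref, alt, compartment = compartment))
}

null_study <- function() {
  cached("null_study",
         suppressWarnings(make_study(study_config(null_combination = TRUE), seed = 404)))
}

# Minimal hand-built expression matrix.
toy_matrix <- function() {
  counts <- matrix(c(10L, 0L, 5L, 20L, 1L, 5L), nrow = 3,
                   dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  expression_matrix(counts, c(gA = 1000L, gB = 500L, gC = 2000L),
                    tibble::tibble(sample_id = c("s1", "s2"),
                                   group = c("CTRL", "DH"),
                                   compartment = "LAC", replicate = c(1L, 1L)))
}

# Hand-built single-cell dataset: counts given explicitly per cell.
toy_sc <- function(counts, cell_types, sample_ids = NULL, groups = NULL,
                   totals = NULL) {
  n <- nrow(counts)
  if (is.null(sample_ids)) sample_ids <- rep("s1", n)
  if (is.null(groups)) groups <- rep("HDM", n)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("g%02d", seq_len(ncol(counts)))
  cells <- tibble::tibble(cell_id = sprintf("c%03d", seq_len(n)),
                          cell_type = cell_types, sample_id = sample_ids,
                          group = groups)
  if (is.null(totals)) {
    totals <- tibble::tibble(sample_id = unique(sample_ids),
                             total_lavage_cells_per_lung = 5e5)
  }
  sc_dataset(counts, cells, totals)
}
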