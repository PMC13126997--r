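Package: lumideconv
Title: Compartment-Resolved Transcriptomics of Co-Exposure Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compartment-resolved bulk and single-cell
    transcriptomic analysis of combination-exposure studies in the airway.
    Implements differential expression scoring (DES, log2 fold change times
    -log10 FDR q), marker-gene-set cell-type interpolation of bulk RNA-seq,
    negative-binomial differential expression with Benjamini-Hochberg FDR,
    combination-specific gene discovery by sign-consistent set logic,
    ligand-receptor co-expression screening of CellPhoneDB-style pair
    tables within and across compartments, and single-cell quantification
    (counts-per-10k normalization, positive-cell rates, per-lung absolute
    scaling). A negative-binomial synthetic-study generator with known
    cell-type composition, synergy genes and ligand-receptor wiring
    provides recovery-testable ground truth for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
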