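# lumideconv

Compartment-resolved transcriptomic analysis of airway co-exposure
studies: what happens when a particulate pollutant and an allergen hit
the lung *together*, and does it happen among the free cells of the
airway lumen (bronchoalveolar lavage; **LAC**) or in the tissue
(**TISS**)?

The package is written for researchers analysing bulk RNA-seq of paired
lavage/tissue samples alongside single-cell molecule counts of lavage
cells, in designs with arms CTRL / particle / allergen /
particle + allergen. It provides, as composable tibble-in, tibble-out
functions:

- **Negative-binomial differential expression** per gene
  (`run_contrast()`, `fit_gene_nb()`): log-link NB GLM with
  median-of-ratios size-factor offsets, per-gene Cox–Reid
  adjusted-profile-likelihood dispersion with empirical-Bayes
  moderation across genes, and a Wald t test on moderation-augmented
  degrees of freedom; Benjamini–Hochberg FDR (`adjust_bh()`), RPKM
  (`compute_rpkm()`), DEG calling at fold/FDR thresholds
  (`call_degs()`), and a control-RPKM sensitivity filter.
- **DES scoring and cell-type interpolation**: the differential
  expression score `DES = log2(FC) × −log10(q)` (`compute_des()`), and
  the estimation of relative cell-type abundance change in bulk data as
  the mean ± SEM of DES over curated marker gene sets
  (`interpolate_cell_types()`), with compartment comparison by
  `delta_des()` and marker validation by `marker_specificity()`.
- **Combination-specific gene discovery**: sign-consistent intersection
  of the combination-vs-single DEG sets (`combination_unique_genes()`,
  `enhanced_beyond_single()`) and cross-particle shared-response genes
  (`cross_particle_common()`).
- **Ligand–receptor screening** of CellPhoneDB-style pair tables within
  a compartment (`screen_pairs_within()`, both partners DE at
  1.25-fold / q < 0.05) and directionally across compartments
  (`screen_pairs_cross()`), with ortholog substitution
  (`map_orthologs()`).
- **Single-cell quantification**: counts-per-10k normalization
  (`normalize_per_cell()`), positive cells per 1000 analysed
  (`positive_cells_per_1000()`), absolute per-lung scaling by lavage
  haemocytometer totals (`cells_per_lung()`, `total_mrna_per_lung()`),
  and unpaired t comparisons (`compare_groups()`).
- A **synthetic-study generator** (`make_study()`) producing bulk and
  single-cell data from known cell-type signature mixtures with
  treatment-dependent composition shifts, injected combination-only
  (synergy) genes and a wired ligand–receptor table — the ground truth
  every recovery test in the package is scored against.

Readers exist for counts TSV/CSV, GMT marker sets, MTX single-cell
triples and CSV pair/ortholog tables; `run_pipeline()` chains all
stages from one YAML config and seed into a results directory with a
checksummed manifest.

## Worked example

```r
library(lumideconv)

study <- make_study(study_config(), seed = 1)   # 2200 genes x 40 samples + 8000 cells

# D+H vs CTRL in the airway lumen
ct <- run_contrast(study$bulk, ref = "CTRL", alt = "DH", compartment = "LAC")
glance(ct)
#> # A tibble: 1 × 8
#>   contrast  compartment n_genes n_deg  n_up n_down fc_threshold q_threshold
#>   <chr>     <chr>         <int> <int> <int>  <int>        <dbl>       <dbl>
#> 1 DH v CTRL LAC            2200   154    98     56            2        0.05

# which cell types drive it?
interpolate_cell_types(ct, study$markers)
#> # A tibble: 10 × 5
#>    cell_type  mean_des sem_des n_genes_used genes_missing
#>    <chr>         <dbl>   <dbl>        <int> <list>
#>  1 AAM        46.1      0.997            20 <chr [0]>
#>  2 Eos        30.4      1.59             20 <chr [0]>
#>  3 Mast       15.8      1.03             20 <chr [0]>
#>  4 RM.Mo       4.58     0.613            20 <chr [0]>
#>  5 Neut        0.00764  0.0215           20 <chr [0]>
#>  6 Bcell      -0.151    0.0645           20 <chr [0]>
#>  7 Tcell      -1.16     0.223            20 <chr [0]>
#>  8 DC         -3.81     0.658            20 <chr [0]>
#>  9 AM        -14.6      1.08             20 <chr [0]>
#> 10 NK        -16.9      1.20             20 <chr [0]>
```

The AAM-like set tops the table: its mean DES of ~46 over 20 marker
genes (SEM 1.0) says those markers moved up together, strongly and
significantly — the bulk signature of that cell type expanding in the
lumen under co-exposure, and indeed the generating truth raised its
fraction from 0.02 to 0.35. Negative scores (resident macrophages, NK)
mark displaced populations. `autoplot()` on either object draws the
volcano / score-bar figures.

Combination-specific genes and the ligand–receptor screen follow the
same grammar:

```r
cu <- combination_unique_genes(
  call_degs(run_contrast(study$bulk, "DEP", "DH", compartment = "LAC")),
  call_degs(run_contrast(study$bulk, "HDM", "DH", compartment = "LAC")))
lr <- screen_pairs_within(
  run_contrast(study$bulk, "HDM", "DH", compartment = "LAC"),
  study$lr_pairs)
```

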