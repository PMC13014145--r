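Package: ramanresist
Title: Single-Cell Raman Phenotyping and Drug-Resistance Likelihood Determination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-cell Raman spectral cytometry of
    tumor and immune cells: spectra input/output on a common wavenumber grid,
    asymmetric-least-squares baseline correction, normalisation and PCA,
    random-forest phenotype classification with Voigt-perturbation wavenumber
    importance, differential Raman "expression" (median log2 fold-change
    barcodes with Wilcoxon rank-sum testing and FDR control), UMAP/Leiden
    cluster composition analysis, and a two-stage mini-patient aggregation
    scheme that converts per-spectrum resistance probabilities into
    patient-level resistance likelihoods with per-drug decision cutoffs.
    Includes a synthetic cohort generator with known ground truth for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    igraph,
    jsonlite,
    pracma,
    ranger,
    Rcpp,
    stats,
    utils,
    uwot
LinkingTo: Rcpp
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
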