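Package: nmrbiomark
Title: Urine 1H-NMR Metabolomics Biomarker Discovery Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biomarker discovery from one-dimensional 1H-NMR urine
    metabolomics: simulation of two-group cohorts and synthetic spectra with
    Lorentzian multiplet structure, TSP referencing, fixed-width spectral
    binning with solvent-region exclusion, metabolite signal integration,
    minimum-positive imputation, geometric-mean normalization and generalized
    log transformation, NIPALS latent-variable models (PCA, two-class PLS-DA
    and OPLS-DA) with R2X/R2Y, cross-validated Q2, variable importance in
    projection (VIP) and permutation validation, Wilcoxon screening with
    Bonferroni adjustment, consensus biomarker selection across models, ROC
    analysis of single markers and marker panels, and hypergeometric
    metabolite-set enrichment against bundled pathway mini-libraries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
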