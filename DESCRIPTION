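Package: longmet
Title: Longitudinal Serum Metabolomics with Multilevel OPLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for paired longitudinal serum
    metabolomics of breast-cancer treatment effects. Provides a seeded
    synthetic cohort generator (clinical table, targeted-MS and NMR metabolite
    blocks, a 105-variable lipoprotein subfraction panel, and frequency-domain
    1D NMR-like spectra with a ground-truth ledger), NMR spectral
    preprocessing (chemical-shift referencing to alanine, baseline offset
    correction, water excision, total-area normalization, region integration),
    targeted-MS quality control (100x-median outlier masking, 30%
    missing/below-LOD exclusion, LOD/2 imputation, coefficients of variation),
    multilevel (paired) OPLS-DA with NIPALS orthogonal filtering, VIP scores,
    patient-grouped cross-validation with first-local-minimum component
    selection and permutation significance testing, and a univariate arm
    (linear mixed models on log concentrations, Wilcoxon signed-rank,
    two-sample t and Fisher exact tests, blockwise Benjamini-Hochberg FDR,
    Friedewald LDL, weight-gain classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr,
    yaml
Config/testthat/edition: 3
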