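# longmet — longitudinal serum metabolomics with multilevel OPLS-DA

`longmet` analyses paired longitudinal metabolomics of breast-cancer
treatment effects: serum profiles measured at baseline and at 6/12 months
after surgery, across three measurement blocks (a targeted-MS kit of 188 raw
/ 140 QC-surviving metabolites, a 30-signal NMR panel, and a 105-variable
lipoprotein subfraction panel). Because such cohorts are small and each
patient is measured repeatedly, the package centres on the **multilevel**
design: for each patient with baseline profile $a_i$ and follow-up profile
$b_i$, the rows $a_i - b_i$ (label $+1$) and $b_i - a_i$ (label $-1$) enter
an OPLS-DA model, cancelling between-patient variation — the multivariate
analogue of the paired t-test.

Around that core the package provides:

* a **seeded synthetic cohort generator** (clinical table, metabolite and
  lipoprotein blocks, frequency-domain NMR-like spectra) with a complete
  ground-truth ledger of every planted effect, censored cell, spike and
  shift offset;
* **NMR preprocessing**: referencing to the alanine doublet at 1.47 ppm,
  baseline zeroing, water excision (4.33–5.13 ppm), total-area normalization
  over 0.29–8.53 ppm, and region integration of 30 metabolite windows;
* **targeted-MS QC**: strict 100×-median outlier masking, exclusion of
  metabolites with >30% missing/below-LOD values, LOD/2 imputation, and
  CoV screening of QC replicates;
* **multilevel OPLS-DA** (NIPALS, one predictive component, label-orthogonal
  filtering), VIP scores, **patient-grouped** 10-fold × 20-iteration
  cross-validation with first-local-minimum component selection, and
  permutation testing with per-patient sign flips
  (p = #{permuted ≥ observed}/n);
* a **univariate arm**: REML linear mixed models on log concentrations,
  Wilcoxon signed-rank, pooled-variance t and Fisher exact tests, blockwise
  Benjamini–Hochberg FDR, Friedewald LDL, and the ≥ 1.5 kg weight-gain
  classification.

## Worked example

Simulate the study-shaped cohort with a planted treatment effect
(21 of the 188 kit metabolites shifted by log(1.35) at 6 months in the 35
chemotherapy recipients), run QC, and test the 6-month response:

```r
library(longmet)

cfg <- cohort_config(seed = 1, ms_fraction = 1,
                     effect_registry = multivariate_shift_registry())
clinical <- generate_cohort(cfg)
mm <- impute_missing(ms_qc_pipeline(
  simulate_metabolite_matrix(clinical, cfg))$matrix)   # 188 -> 140 columns
chemo <- clinical$patient_id[clinical$chemo]
ds <- build_paired_dataset(mm[mm$sample_meta$patient_id %in% chemo, ], 0, 6)

cv <- cross_validate(ds, max_orth = 2, n_folds = 10, n_iter = 5, seed = 1)
pt <- permutation_test(ds, max_orth = 2, n_folds = 10, n_iter = 5,
                       n_perm = 200, seed = 1)
print(cv)
print(pt)
```

```
<cv_result> chosen n_orth = 0, accuracy = 0.966 (sens 0.966 / spec 0.966)
<permutation_result> observed accuracy 0.966, p = < 0.005 (200 permutations)
```

Cross-validated accuracy is the balanced accuracy over patient-grouped folds
(here 96.6%: nearly every held-out patient's direction of change is
classified correctly), and the permutation p says no label-permuted refit
matched it in 200 tries. `fit_opls_da()` + `vip_scores()` on the full data
rank the planted variables at the top: 20 of the 21 planted metabolites land
in the VIP top-21 (`analysis/04_multilevel_models.R`).

The numbered scripts under `analysis/` run the whole study-shaped sequence —
`01_simulate`, `02_preprocess_nmr`, `03_qc_ms`, `04_multilevel_models`,
`05_univariate`, `06_full_report` — each a thin driver over the package
functions, writing its tables under `results/`.

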