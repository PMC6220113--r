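---
title: "Multilevel OPLS-DA for paired longitudinal serum metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel OPLS-DA for paired longitudinal serum metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longmet)
```

# The problem

Serum metabolomics of patients under treatment produces two or three
multivariate measurements per patient. The scientifically interesting signal
— how an individual's metabolite profile changes between baseline and
follow-up — is small compared to the stable between-patient differences in
absolute concentrations. `longmet` implements the paired ("multilevel")
analysis that removes the between-patient level before classification, plus
everything such an analysis needs around it: spectral preprocessing for
NMR-derived panels, quality control for targeted mass-spectrometry kits, a
univariate mixed-model arm, and a synthetic cohort generator with a complete
ground-truth ledger so every stage can be tested without access to patient
data.

# The multilevel design

Let $A$ be the matrix of baseline profiles and $B$ the matrix of follow-up
profiles over the patients with both measurements. Each patient contributes
two mirrored rows, $a_i - b_i$ labelled $+1$ and $b_i - a_i$ labelled $-1$.
Between-patient variation cancels in the differences, making the OPLS-DA
discrimination of $+1$ from $-1$ a multivariate analogue of the paired
t-test. `build_paired_dataset()` constructs this design and enforces its
invariants: mirrored rows negate exactly, classes are balanced, and a
patient missing either timepoint is excluded and listed.

# OPLS-DA

`fit_opls_da()` is a NIPALS implementation of orthogonal projections to
latent structures for a two-class $\pm 1$ response $y$. Each orthogonal
round computes the predictive direction $w \propto X^\top y$ ($\lVert w
\rVert = 1$), scores $t = Xw$ and loading $p = X^\top t / t^\top t$, splits
the label-orthogonal part of the loading off as $w_o \propto p - (w^\top p)
w$, and deflates $X \leftarrow X - t_o p_o^\top$ with $t_o = X w_o$. After
`n_orth` rounds one predictive component is fitted on the filtered matrix.
Two consequences are asserted in the tests: every orthogonal score has zero
sample correlation with $y$, and with `n_orth = 0` the model is exactly a
one-component PLS1 regression (checked against a closed-form oracle and
against an independent PLS implementation).

One predictive component is always used — for a two-class problem the
discriminating subspace is one-dimensional — and only the number of
orthogonal components is selected by cross-validation. Variable importance
follows the usual VIP definition; because orthogonal components explain no
label variance, the score reduces to $\sqrt{p}\,\lvert w_j \rvert$ on the
predictive weights and squared VIPs average to exactly 1.

Scaling is a modelling choice the source protocol leaves open: the default
is autoscaling (mean-centre, unit variance), switchable to centring only via
`unit_variance = FALSE`. Zero-variance columns are centred, flagged and not
divided. The scaling recipe is always refit inside each training fold.

# Validation

`cross_validate()` runs 10-fold cross-validation with 20 random fold
assignments by default. Folds partition *patients*, never rows: both
mirrored rows of a patient share a fold, otherwise the mirror of a training
row would appear in the test set and accuracy would be absurdly optimistic.
For unpaired designs (e.g. predicting weight gain from baseline profiles)
folds are stratified by class. Classification error is $1 -
(\text{sensitivity} + \text{specificity})/2$, which under the balanced
multilevel design equals the raw error rate. The number of orthogonal
components is the **first local minimum** of the mean error curve over
`0..max_orth`, with ties broken toward fewer components and a strictly
decreasing curve yielding the last index. `max_orth` defaults to 3; the
protocol does not state the searched range, and on 30-140 variable panels
with ≤ 60 patients more orthogonal filtering than that only overfits.

`permutation_test()` reruns the whole cross-validation (including component
selection, by default; `fix_n_orth` freezes it) on label-permuted data.
Permutations respect the design: for multilevel data each patient's
difference vector keeps or flips its sign — equivalently the pair swaps its
labels — which preserves the antisymmetric structure; shuffling rows
independently would break it and deflate the null. For unpaired data, labels
are shuffled across patients. The p value is the plain proportion of
permuted accuracies at or above the observed one, so the smallest reportable
value is $1/n_\text{perm}$ and an exceedance count of zero is printed as
`< 1/n_perm`. The suite verifies calibration directly: on 200 null cohorts
(40 patients, 50 variables, 99 permutations each) the 0.05-level rejection
rate stays within $0.05 \pm 0.04$ and the p values pass a
Kolmogorov–Smirnov uniformity check.

# NMR preprocessing

`preprocess_spectrum()` chains the four protocol steps on a frequency-domain
spectrum: reference the axis so the left (higher-ppm) line of the alanine
doublet sits at 1.47 ppm; subtract a constant so the minimum intensity is
zero; flag the water residual window 4.33–5.13 ppm so excised points
contribute nothing to any later area; and divide by the trapezoidal area
over the retained points of 0.29–8.53 ppm so every spectrum has unit total
area. Two conventions had to be fixed where the protocol is silent: all
windows are closed intervals (a point exactly on a bound belongs to the
window), and "equal total area" is taken as area 1.

Doublet detection looks for two local maxima in 1.40–1.55 ppm rising at
least five times the window noise above the window median, separated by
0.005–0.03 ppm; the noise level is the median absolute deviation of
successive differences, so structured signal drifting into the window (the
lipid methylene tail, under negative shifts) does not inflate the threshold.
Among separation-compatible pairs the one whose *weaker* line is tallest
wins: true doublet lines have comparable height, chance pairs of noise bumps
do not.

Quantification is plain trapezoidal integration over configured windows —
no lineshape fitting — with multi-window metabolites combined by mean or by
a designated single window. Only the two lipid windows (0.8–0.9 and
1.55–1.60 ppm) are fixed by the protocol; the other 28 default windows in
`default_region_table()` bracket the synthetic peak positions and are
explicitly editable configuration, because the original integration table is
not public.

# Targeted-MS quality control

`ms_qc_pipeline()` applies three rules in a fixed, idempotent order:

1. **Outlier masking**: entries strictly above 100× the column median
   (median over observed, non-censored cells, so spikes cannot raise their
   own threshold) become missing.
2. **Metabolite exclusion**: columns whose *pooled* fraction of
   missing-or-below-LOD cells strictly exceeds 30% are dropped. The source
   rule can also be read as two separate thresholds; the pooled reading is
   implemented and both fractions are reported per column so either rule can
   be audited.
3. **LOD/2 imputation**: censored cells become half the column's limit of
   detection; nothing else changes. Below-LOD cells are carried as an
   explicit censored state up to this point, never as numbers.

`compute_cov()` reports 100·sd/mean per column over QC replicates (sample
sd), with flags at 15% and 25%. For the multivariate arm, which needs
complete rows, `impute_missing()` fills residual missing cells with column
medians; the mixed-model arm keeps its NAs — tolerance for unbalanced data
is the reason a mixed model is used at all.

# Univariate arm

`lmm_time_effect()` fits natural-log concentrations with a fixed categorical
timepoint effect and a random per-patient intercept by REML (`nlme`), giving
a Wald p for the time coefficient. This is the minimal model matching
"time-related trends with missing-value tolerance"; covariate adjustment is
deliberately out of scope. On complete balanced data the estimate equals the
mean within-patient log difference (asserted to 1e-8), and data with no
within-patient variance are degenerate for REML, returned as estimate 0,
p 1, flagged. Lipoprotein subfractions use Wilcoxon signed-rank tests
(exact null for ≤ 25 tie-free non-zero differences, normal approximation
with continuity correction otherwise); cohort-description comparisons use
pooled-variance two-sample t and Fisher exact tests (two-sided by the
point-probability rule). FDR control is Benjamini–Hochberg, applied within
each measurement block (MS, NMR, lipoproteins) separately — a block's q
values never depend on another block's p values. Natural log is used
throughout; the base only rescales estimates.

`friedewald_ldl()` computes LDL as tc − hdl − tg/2.2 (mmol/L), refusing
tg ≥ 4.5. `classify_weight_gain()` labels a patient a gainer at a 6-month
increase of **at least** 1.5 kg (boundary inclusive) and `unknown` when the
6-month weight is missing.

# The synthetic cohort generator

Every quantity the pipeline consumes can be simulated from a single seeded
`cohort_config()`, and every injected artefact is recorded in a truth
ledger, so tests compare pipeline output against known ground truth rather
than against itself.

* **Design**: 60 patients, 35 chemotherapy recipients, visits at 0/6/12
  months; the MS kit covers 53 patients at 0/6 months; 8 patients lack
  follow-up weights, and 17 of the 52 evaluable patients gain ≥ 1.5 kg.
  Group sizes follow `round(n · fraction)` exactly. Covariate frequencies
  (menopausal status, Herceptin, radiation, surgery, endocrine therapy) are
  allocated as exact per-group counts matching the reference cohort's
  cross-tabulations, which `reference_contingency_tables()` exposes.
* **Concentrations** are log-normal with a per-patient random intercept:
  with total log-scale sd $\sigma$ and intraclass correlation $\rho$, the
  intercept has sd $\sqrt{\rho}\,\sigma$ and the residual
  $\sqrt{1-\rho}\,\sigma$. Defaults $\sigma = 0.4$, $\rho = 0.5$ are free
  parameters chosen as typical for serum metabolite panels — the source
  protocol reports no variance components — and are recovered by a
  variance-components oracle within ±0.05 in the tests.
* **Effects** are additive on the natural-log scale per
  (variable, group, timepoint); the default registry plants the kynurenine
  response (+38% at 6 months under chemotherapy, +25% without).
  `multivariate_shift_registry()` builds the power scenario: log(1.35) on
  21 spread-out kit variables.
* **Pathologies (MS block)**: the LOD is the empirical `lod_quantile` of
  each column (default 5%), censoring exactly `round(q·n)` cells; 48
  designated columns are censored at 40% so the 30% rule removes exactly
  them, taking 188 raw columns to 140 — deterministic by construction, and
  the truth ledger names them. MCAR missingness (2%) and multiplicative
  spikes drawn uniformly in 150–500× the column median (0.5%) — safely
  beyond the 100× masking threshold — are layered on top. Effect-registry
  variables are never designated low-quality, so planted signals survive QC.
* **Weight trajectories**: gainer status is assigned first and the 6-month
  delta drawn from a truncated normal on the matching side of 1.5 kg, so
  the label is exactly consistent with the rule. Lipids are built as
  TG, HDL, LDL draws with TC as their Friedewald-consistent sum.
* **Spectra**: each sample's spectrum is the sum of Lorentzian peaks with
  areas equal to its simulated concentrations (the default peak table gives
  each of the 30 signals its components, including the alanine doublet with
  the left line at 1.470 ppm), a compactly supported water hump inside
  4.38–5.08 ppm, a constant baseline offset, white noise, and one global
  shift offset per sample recorded in truth. The axis is descending,
  32768 points over [−0.5, 10] ppm, sampling the 0.0015-ppm linewidths with
  ~5 points.
* **Lipoproteins**: the 105-code schema crosses prefixes
  {TP, V1–V5, ID, L1–L6, H1–H4} with contents {TG, CH, FC, PL, A1, A2, AB},
  omitting A1/A2 in VLDL subfractions and AB in HDL subfractions. The true
  panel composition is proprietary and its published description names only
  the grammar, the count (105) and the exclusion of VLDL-6, so this exact
  composition is a synthetic convention. One latent factor per particle
  class makes within-class correlations exceed between-class ones.

What the generator does **not** emulate: time-domain FIDs, phase or
apodization artefacts, the proprietary lipoprotein regression itself,
correlated (non-MCAR) missingness, drift between analytical batches, or any
pharmacokinetics. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under a known generative model — not
that the original study's numbers are reproduced, which is impossible
without the undeposited serum data.

# Numerical choices and degenerate inputs

* Trapezoidal areas never bridge excised points: integration runs over
  contiguous retained segments only, with interpolated values at exact
  window bounds.
* `fit_opls_da()` errors when the orthogonal residual rank is exhausted, and
  when $X^\top y$ is numerically zero (no predictive direction).
* Component selection ties break toward fewer components.
* All randomness derives from one user seed via tagged sub-streams
  (`derive_seed`), so fold assignment, permutations and each simulated block
  are decoupled: changing `n_perm` never changes the folds.
* Scaled-down defaults in the shipped analyses: the calibration study uses
  200 null cohorts at 99 permutations with single-iteration CV; the power
  scenario uses 5 CV iterations and 200 permutations. These sizes give
  stable estimates of a rate/accuracy while keeping the scripts quick; the
  per-analysis knobs are all exposed.

# A worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 1, ms_fraction = 1,
                     effect_registry = multivariate_shift_registry())
clinical <- generate_cohort(cfg)
mm <- impute_missing(ms_qc_pipeline(
  simulate_metabolite_matrix(clinical, cfg))$matrix)
chemo <- clinical$patient_id[clinical$chemo]
ds <- build_paired_dataset(mm[mm$sample_meta$patient_id %in% chemo, ], 0, 6)
cv <- cross_validate(ds, max_orth = 2, n_iter = 5, seed = 1)
pt <- permutation_test(ds, max_orth = 2, n_iter = 5, n_perm = 200, seed = 1)
```

The numbered scripts under `analysis/` run the full study-shaped sequence —
simulation, NMR quantification, MS QC, the multilevel models and the
univariate arm — and write their tables under `results/`.

# Known limitations

* The integration region table beyond the two lipid windows is synthetic
  configuration; real spectra need a curated table.
* Column-median imputation of residual missingness in the multivariate arm
  is simple and can attenuate signal under informative missingness.
* The permutation test reruns component selection per permutation
  (conservative); fixing the component count is available but not default.
* No multi-class OPLS-DA, no O2-PLS, and no double cross-validation.
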