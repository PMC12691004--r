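# dosederm

Dose-guided hybrid radiomics for predicting Grade ≥ 2 radiation dermatitis
(RD) after breast volumetric modulated arc therapy (VMAT).

Acute skin toxicity is the most common side effect of breast radiotherapy,
and models built on clinical covariates and dose–volume histogram (DVH)
parameters alone discriminate poorly. This package implements, as a tested R
pipeline, a hybrid approach whose central idea is a **dose-guided region of
interest**: deep and handcrafted imaging features are extracted not from the
whole CT or a fixed anatomical shell, but from

> DLR_V5Gy = skin5mm ∩ { x : D(x) ≥ 5 Gy },

the subcutaneous layer within 5 mm of the body surface restricted to tissue
actually receiving at least 10 % of the 50 Gy prescription. Around that core
the package provides the full analysis chain:

* **RT data model** — DICOM CT / RT-STRUCT / RT-DOSE ingestion (purpose-built
  explicit-VR subset codec), contour rasterization by voxel-centre even-odd
  parity, trilinear dose resampling, anisotropic 3-D skin margins, and the 12
  DVH features (skin5mm V5–V50Gy, PTV100%, PTV105%).
* **Feature extraction** — 105 handcrafted radiomic features per ROI (14
  shape, 18 first-order, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM;
  3-D, direction-averaged, fixed 25 HU bins) and 4224 deep features per
  patient from a frozen 13-convolutional-layer VGG-topology extractor with
  global average pooling after every layer, for four input designs
  (original, skin5mm, PTV100%, V5Gy).
* **Selection and modelling** — per-block two-stage selection (one-way ANOVA
  at p < 0.05, then a Boruta-style shadow procedure scored by exact TreeSHAP
  importances over 200 iterations); SMOTE–ENN rebalancing inside training
  folds; a stacking ensemble (ridge logistic regression, random forest,
  gradient-boosted trees; logistic meta-learner on out-of-sample base
  probabilities) tuned by randomized search under stratified 5×5 nested
  cross-validation; ablation and hyperparameter-sensitivity reports.
* **Evaluation and explainability** — confusion-matrix metrics with t-based
  fold CIs, Mann–Whitney AUC, Brier score, Cohen's d, decision-curve
  analysis with Youden operating points, permutation-SHAP attributions and
  Grad-CAM saliency through a logistic probe on the frozen extractor.
* **Synthetic cohort** — a seeded thorax-phantom generator reproducing the
  modeled study conditions (148 patients, 33.1 % prevalence, published
  covariate marginals and DVH distributions) with a known logistic
  dose/texture→label link, so selection recovery, leakage control and
  calibration are testable without patient data.

## Worked example

```r
library(dosederm)

# a seeded cohort at the study conditions, with the planted-signal effect
# sizes used by the recovery analyses (dose effect 1.0 SD, IMN 0.8)
cohort <- generate_cohort(cohort_config(
  n_patients = 148, seed = 1,
  betas = c(b0 = NA, age = 0.35, imn = 0.8, v25 = 1.0, texture = 0.3)))
mean(cohort$clinical$rd_grade_ge2)
#> [1] 0.3513514

# nested cross-validation of the stacking ensemble, clinical + DVH block
blocks <- list(clinical = encode_clinical(cohort$clinical), dvh = cohort$dvh)
res <- run_nested_cv(blocks, cohort$clinical$rd_grade_ge2, combination = 1,
                     nested_cv_config(n_draws = 10,
                                      select_blocks = character(0), seed = 1))
round(res$report$summary["auc", ], 3)
#>  mean   low  high
#> 0.661 0.567 0.756
```

The per-fold AUCs average 0.661 with a 95 % t interval across the five outer
folds of (0.567, 0.756): the planted dose–label association is recovered
well above the permutation-null level of 0.5, with fold-level spread typical
of 30-patient test folds. At the package's *default* effect sizes — chosen
to mirror the modest published univariate contrasts — the same run sits much
closer to 0.5, which is exactly the regime the published clinical + DVH
baseline reports.

The numbered scripts under `analysis/` run the full narrative — cohort
simulation, DICOM round-trip, ROI/DVH/HCR/DLR extraction, cohort statistics,
selection, modelling, decision curves, SHAP and Grad-CAM — writing tables
under `results/`. For example, `analysis/03_cohort_stats.R` recomputes the
published group comparisons from the printed summaries (Pearson chi-square
without continuity correction; pooled-variance t), reproducing the printed
p-values: IMN irradiation p = 0.033, laterality p = 0.323, chemotherapy
p = 0.600; PTV100% p = 0.013, skin V25Gy p = 0.048, V45Gy p = 0.046,
V50Gy p = 0.366.

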