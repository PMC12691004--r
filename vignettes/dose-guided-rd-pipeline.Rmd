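---
title: "Dose-guided hybrid radiomics for radiation dermatitis risk: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-guided hybrid radiomics for radiation dermatitis risk: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosederm)
```

## The problem

Grade ≥ 2 radiation dermatitis (RD) is the most frequent acute toxicity of
breast VMAT. Risk models built only on clinical covariates and dose–volume
histogram (DVH) parameters discriminate poorly; this package implements a
hybrid pipeline in which imaging features are extracted from a *dose-guided*
region of interest — the subcutaneous layer within 5 mm of the skin surface,
intersected with the region receiving at least 5 Gy (10% of the 50 Gy / 25
fraction prescription) — and fused with clinical and DVH blocks in a stacking
ensemble under nested cross-validation.

Because the source cohort is access-restricted, the package ships a synthetic
thorax-phantom generator whose statistical structure mirrors the published
cohort. Every pipeline stage is exercised against it, with known ground
truth, rather than against patient data.

## Geometry and regions of interest

Grids are axis-aligned (identity orientation; oblique acquisitions are
rejected at the DICOM boundary). Voxel membership in a contour is decided by
the voxel centre against the polygon with even-odd parity, matching common
treatment-planning-system rasterization and making the operation checkable
against a brute-force point-in-polygon oracle. Volumes are reported in cc as
`count * voxel_volume_mm3 / 1000`.

* **body** — CT threshold at −300 HU, largest 6-connected component,
  slice-wise hole filling (so lung stays inside the body).
* **skin5mm** — body voxels whose centre lies within 5 mm *anisotropic
  Euclidean* distance of the nearest non-body voxel centre. A true 3-D
  distance margin is used rather than slice-wise 2-D erosion because at
  2.5 mm slice spacing 2-D erosion is strongly anisotropic.
* **v5gy** — `skin5mm ∧ (dose ≥ 0.10 × prescription)`, thresholds inclusive,
  dose first resampled to the CT grid by trilinear interpolation (exact on
  affine fields; 0 Gy outside the dose extent).
* **PTV100%/PTV105%** — PTV sub-volumes receiving ≥ 100% / ≥ 105% of
  prescription.

The 12 DVH features are the absolute skin5mm volumes at 5–50 Gy in 5 Gy
steps plus the two PTV sub-volumes; monotonicity of V5 ≥ V10 ≥ … ≥ V50 is a
tested invariant.

## Handcrafted radiomics (105 features)

`extract_hcr()` computes 14 shape, 18 first-order and 73 texture features
(22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) per ROI:

* Discretisation is fixed-bin-width, default 25 HU (configurable); the level
  map is `floor((I − min)/width) + 1`.
* GLCM and GLRLM are built in 3-D over the 13 unique distance-1 direction
  offsets and features are averaged over directions; GLSZM zones use
  26-connectivity; GLDM/NGTDM use the 26-voxel neighbourhood. GLDM
  dependence size counts the centre voxel plus its equal-level neighbours
  (so it is at least 1 and small-dependence emphasis is always defined).
* The 22-name GLCM set is the standard 24-feature family minus SumAverage
  (identical to twice JointAverage under symmetric co-occurrence) and MCC —
  the two members most commonly disabled; the full 105-name manifest is
  frozen in `hcr_feature_names()`.
* Degenerate denominators (constant ROI, single gray level) return 0 rather
  than NaN; NGTDM coarseness of a flat region returns the conventional cap
  1e6. Shape descriptors are voxel-based: surface area from exposed faces,
  mesh volume equal to the voxel volume, axis lengths from the PCA of voxel
  centres, maximum diameters from convex-extreme candidate points (exact for
  convex bodies).

Tested properties: intensity-shift invariance of texture on fixed-width
bins, invariance of direction-averaged features under 90° in-plane rotation,
finiteness on fuzzed inputs, and hand-enumerated co-occurrence and run
matrices on checkerboard and line fixtures.

## Deep features (4224 per input design)

The extractor is the 13-convolution topology of the standard 16-layer VGG
network: 3×3 kernels, stride 1, padding 1, ReLU, 2×2 max-pooling after
layers 2, 4, 7, 10 and 13, channel widths 64–512 summing to 4224. Global
average pooling after every convolution yields the per-slice vector;
per-patient vectors are means over eligible slices. Convolution is evaluated
as nine shifted BLAS matrix products, so extraction requires no
deep-learning runtime.

Weights are **frozen**. The default mode draws them once from a seeded
He-scaled normal distribution: this keeps the full pipeline — masking,
pooling, aggregation, selection, modelling — mechanically exercisable and
bit-reproducible without any download, while externally trained weights can
be plugged in as a list of arrays. What random weights cannot show is the
*semantic* value of transfer-learned features; conclusions from the
synthetic tests concern pipeline correctness, not pretrained-feature
quality.

Slice preparation windows HU to [−1000, 1000], scales to [0, 1], zero-fills
outside the ROI for masked designs (`skin5mm`, `ptv100`, `v5gy`;
`original` takes the unmasked slice), centre-pads to the configured input
size and replicates to three channels. The default per-channel
normalisation constants are identity (mean 0, scale 1): the study's
constants are unpublished, and identity keeps the masked background exactly
zero, which the off-mask invariance test relies on. Masked designs require
an ROI area of at least 16 pixels per slice; `original` uses slices within
the body's axial extent.

## Two-stage feature selection

Stage 1 is a one-way ANOVA per feature at p < 0.05 — with a binary outcome
this is exactly the two-group F test, numerically the square of the pooled
two-sample t (a tested identity). Zero-variance features get p = 1.

Stage 2 is a Boruta-style shadow wrapper: per iteration every column is
independently permuted to create shadows, a depth-unlimited random forest is
fitted on `[real | shadow]`, per-feature importance is the mean absolute
TreeSHAP value, and a real feature scores a hit when it beats the best
shadow. After `n_iter` rounds (default 200) a two-sided binomial test
against Binomial(n_iter, ½) at α = 0.05 declares accepted / rejected /
tentative; tentative is treated as rejected at the modelling boundary so
fitted feature sets are reproducible. The forest is xgboost in
random-forest configuration (one boosting round, 200 parallel trees,
subsample 0.632, √p column sampling per node, unlimited depth), whose
`predcontrib` predictions are exact TreeSHAP values.

Both radiomic and clinical/DVH blocks pass through both stages by default;
`nested_cv_config(select_blocks = ...)` can exempt blocks. For the low-dimensional
clinical + DVH combination the pass-through mode is the sensible analysis
choice: the two-stage screen exists to tame the 4224-dimensional radiomic
blocks, and on ten strongly correlated skin V-levels the shadow procedure
splits TreeSHAP importance across the collinear profile so that entire
blocks can drop out of single folds. The package's recovery analyses
therefore run the clinical + DVH combination with pass-through and exercise
selection behaviour in dedicated tests (null false-acceptance ≤ 5%, stable
acceptance of planted predictors).

## Rebalancing and the stacking ensemble

SMOTE synthesises minority samples `x_i + u (x_nn − x_i)` (u ~ U(0,1),
`x_nn` among the 5 nearest minority neighbours) until the classes balance;
ENN then removes samples whose 3 nearest neighbours' majority vote
disagrees with their label. Both run strictly inside training folds. On
heavily overlapping classes ENN can gut a class; if a class would fall
below 6 samples the editing step is skipped for that fold so the fold stays
trainable.

The ensemble stacks ridge logistic regression, a random forest (ranger) and
gradient-boosted trees (xgboost) under a logistic meta-learner. Randomized
search (default 30 draws per learner) scores configurations by mean
inner-fold AUC — AUC being the study's primary metric — while the
sensitivity tables aggregate F1 per sampled value of `n_estimators`,
`max_depth` and `learning_rate`. The logistic-regression search draws its
ridge penalty log-uniformly from 10^[−2, 10^0.5]: at n ≈ 150 z-scored
features, penalties below 10^−2 are indistinguishable from unregularised
fits and waste draws. The meta-learner is trained on 5-fold out-of-sample
base probabilities (classic leak-safe stacking) and carries a small ridge
penalty (λ = 0.02) because the three base probabilities are strongly
correlated and an unpenalised fit is numerically unstable at fold sizes.

Nested cross-validation uses stratified 5×5 folds: outer test folds
partition the patients with per-fold positive counts within one of the
global fraction; selection, z-scoring, rebalancing and search all happen
inside the outer-training data. Leak-freedom is enforced structurally (fold
ids carried by selection reports and asserted at fusion) and tested
adversarially (replacing test-fold rows with noise leaves the fitted fold
model bit-identical). When selection leaves no features in a fold, the fold
falls back to a constant predictor at the training prevalence — the same
saturated behaviour that degenerate tree models show on small cohorts — so
null-signal simulations stay well-defined.

## Evaluation

Accuracy, recall, specificity, PPV, NPV and F1 follow the standard
confusion-matrix formulas with fixed conventions for empty denominators
(PPV = 0 if TP+FP = 0, NPV = 0 if TN+FN = 0, F1 = 0 if PPV+recall = 0). AUC
is the Mann–Whitney statistic with half-credit ties. Per-metric 95%
confidence intervals over the k outer folds use the t distribution with
k − 1 degrees of freedom; between-model effect sizes are Cohen's d with
pooled SD. The Brier score accompanies every report.

Decision-curve analysis reports net benefit `TP/n − (FP/n)·t/(1−t)` against
treat-all and treat-none policies, and clinical utility (PPV, NPV, FPR, FNR)
at both the 0.5 and Youden-index thresholds.

For the published cohort tables, the package recomputes group comparisons
from the printed summaries: Pearson chi-square **without** continuity
correction on the clinical contingency tables, and pooled-variance Student
t from (mean, SD, n) for the DVH rows. These two choices reproduce the
printed p-values to their printed precision (0.033, 0.323, 0.600, 0.861,
0.077; 0.013, 0.048, 0.046, 0.366); Welch's t does not. One DVH row (V30,
printed 0.049) recomputes to 0.050 under the pooled t — consistent with
rounding of unprinted precision — and is reported but not asserted. Age and
BMI comparisons are not recomputable because the publication prints no SD
for them.

## Explainability

SHAP attributions for the stacked predictor use permutation sampling with
telescoping marginal contributions: along each sampled feature permutation,
coordinates switch one at a time from a sampled background row to the
explained row, and consecutive prediction differences are credited to the
switched feature. The telescoping sum makes local additivity exact per
draw, so `base_rows + rowSums(phi)` equals the model output to floating
point. TreeSHAP is not used here because the stacked predictor is not a
single tree model.

Grad-CAM needs a differentiable scalar head, and the stacked ensemble is
not differentiable; the head is therefore a ridge logistic probe on the GAP
features (`fit_dlr_probe()`). The gradient of the probe logit with respect
to a layer's post-activation map is taken through that layer's own GAP
term — giving channel weights `w_c = probe_weight_c / (H·W)` — with
deeper-layer paths treated as stopped gradients. This choice makes the
one-hot-probe case exactly analytic (the map is the ReLU-clipped channel
activation) and keeps the saliency attributable to the inspected layer. The
map is bilinearly upsampled and normalised to [0, 1]; overlap with a
reference mask is the Dice coefficient of the top-quantile pixels.

## The synthetic cohort: what it does and does not emulate

Defaults reproduce the modeled study conditions: 148 patients, target
prevalence 0.331, 50 Gy prescription, published covariate marginals
(laterality 0.473 left, breast-conserving surgery 0.804, supraclavicular
irradiation 0.257, internal-mammary irradiation 0.223, chemotherapy 0.50,
the printed AJCC distribution), age mean 56 and BMI mean 24.73. The
publication prints no SD for age or BMI; the defaults (10 and 3.5) are
package choices typical of breast-radiotherapy cohorts. Labels are drawn
from a logistic model on z-scored age, IMN irradiation, skin V25Gy and a
latent texture correlation length — *covariates, not raw pixels* — so that
"signal features" are known ground truth for selection- and
recovery-testing. The intercept is auto-calibrated by bounded bisection of
the Monte-Carlo mean risk to the target prevalence (tolerance 0.005).
Default effect sizes (0.35 per SD age, 0.6 IMN, 0.35 per SD V25, 0.3 per SD
log-texture) give group contrasts of the same order as the published
univariate comparisons; recovery tests raise V25 and IMN to 1.0 and 0.8 as
their planted-signal condition.

Two generation paths share this covariate/label model. The **image path**
builds a star-shaped thorax section with a breast-like lateral bulge
(soft-tissue 40 HU plus a seeded spectral-synthesis Gaussian random field
whose correlation length is the patient's latent texture scale; −750 HU
lung ellipsoids), a PTV in the bulge, and a tangential-style dose field —
prescription times a logistic fall-off in PTV distance, normalised to the
prescription at the PTV surface, amplitude ≤ 1.08 so dose never exceeds
1.15 × prescription — written to DICOM through the package's own codec. The
default 96×96×24 grid at (2, 2, 2.5) mm is a deliberately scaled-down
section, so its absolute skin volumes are cc-scale rather than the
published hundreds of cc; the label link standardises V25 against the
realized cohort so planted effects are per cohort SD at any scale. The
**tabular path** draws the DVH profile directly from a parametric
surrogate — a patient-level lognormal scale on the published mean profile
with a dose-tail tilt and enforced monotonicity — matching the published
means and SDs, and runs at n in the hundreds in milliseconds; large-n null
and calibration simulations use it.

Not emulated: anatomical realism, beam models or Monte-Carlo dose
transport, CT artifacts, inter-observer contouring variation, and any
pixel-level association between CT texture and outcome (the texture–label
link is through the latent correlation length). Passing tests therefore
demonstrate that the pipeline recovers signal that is present and stays
null when it is absent — not that the published effect sizes are correct,
and not that pretrained deep features are clinically informative.

## Problem sizes used by the test-suite analyses

Cohort simulations use n = 148 (the study size) for recovery and
permutation-null runs, n = 500–2000 (tabular path) for marginal and
calibration checks, and 10–12 image phantoms at 48³–96² grids for the
geometric stages. The deep extractor runs at input sizes 16–96 in tests and
at the native 512 in the acceptance script. Nested-CV tests use 2–10 search
draws per learner; analysis scripts use 10; the package default is 30.

## Known limitations

* The DICOM codec is a purpose-built subset (explicit VR little endian; CT,
  RT-DOSE, RT-STRUCT with defined-length sequences). It round-trips the
  package's own cohort layout and standard-shaped files of that subset; it
  is not a general DICOM toolkit.
* Shape descriptors are voxel-based approximations, not mesh-based; surface
  area from exposed faces overestimates smooth surfaces.
* With strongly collinear feature blocks the shadow-based selection spreads
  importance and can reject every member of a correlated informative group;
  the pass-through toggle exists for exactly this situation.
* Seeded-random extractor weights exercise mechanics, not transfer
  learning; conclusions about pretrained-feature value require external
  weights.
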