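Package: dosederm
Title: Dose-Guided Hybrid Radiomics for Radiation Dermatitis Risk Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for predicting Grade >= 2 radiation
    dermatitis after breast volumetric modulated arc therapy from planning
    CT, RT structure sets and RT dose grids. Builds dose-guided skin regions
    of interest (the 5 mm subcutaneous layer intersected with the >= 5 Gy
    isodose), computes dose-volume histogram parameters, extracts 105
    handcrafted radiomic features and 4224 frozen-CNN global-average-pooled
    deep features, performs two-stage feature selection (one-way ANOVA then
    a Boruta-style shadow-feature procedure scored by TreeSHAP importances),
    rebalances training folds with SMOTE-ENN, and fits a stacking ensemble
    (logistic regression, random forest, gradient-boosted trees with a
    logistic meta-learner) under nested stratified cross-validation.
    Includes a synthetic thorax-phantom cohort generator with a known
    dose/texture-to-label link so that feature recovery, leakage control and
    calibration are testable without patient data, plus permutation-SHAP and
    Grad-CAM explainability and decision-curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
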