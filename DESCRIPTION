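Package: fetalens
Title: Ensemble Prediction of Fetal Macrosomia and Large-for-Gestational-Age
    from Longitudinal Ultrasound Biometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-step ensemble-learning workflow for predicting fetal
    macrosomia (birth weight > 4000 g) and large-for-gestational-age (LGA)
    infants from serial prenatal ultrasound biometry. Step 1 converts
    biparietal diameter, middle abdominal diameter and femur length into
    estimated fetal weights through a bank of 26 published sonographic
    formulas; Step 2 fits subject-specific growth curves with a
    three-parameter logistic nonlinear mixed-effects model (heteroscedastic
    power-of-the-mean errors) or a quadratic linear mixed-effects model and
    predicts birth weight from empirical-Bayes random-effect modes; Step 3
    converts predicted birth weights into binary macrosomia and LGA
    classifications; Step 4 combines the resulting panel of learners by
    majority voting or super-learner stacking, with LASSO, SCAD or MCP
    penalized-regression learner selection. Includes a calibrated synthetic
    cohort generator emulating a Scandinavian birth cohort, bespoke
    penalized and positivity-constrained logistic/linear solvers, and
    diagnostic-accuracy reporting (AUC, sensitivity, specificity,
    predictive values, likelihood ratios, Youden's index) with confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    nlme,
    MASS,
    pROC,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
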