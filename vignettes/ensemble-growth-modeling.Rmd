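---
title: "Predicting macrosomia and LGA from serial ultrasound biometry: models, ensembles, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting macrosomia and LGA from serial ultrasound biometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A macrosomic infant weighs more than 4000 g at birth; a
large-for-gestational-age (LGA) infant sits above the 90th birth-weight
percentile for its gestational age. Predicting either condition before
delivery from routine prenatal ultrasound supports obstetric decisions
about monitoring and mode of delivery. The available inputs are sparse
longitudinal biometry — biparietal diameter (BPD), middle abdominal
diameter (MAD) and femur length (FL), measured at roughly the 17th, 25th,
33rd and 37th gestational weeks — plus baseline maternal covariates and,
at evaluation time, the gestational age at delivery.

`fetalens` implements a four-step procedure for this prediction task:

1. **EFW.** Convert each visit's biometry into an estimated fetal weight
   (EFW) through one of 26 published sonographic formulas.
2. **Growth model.** Fit a mixed-effects growth model to each subject's
   EFW series plus (for training subjects) the observed birth weight, and
   predict the birth weight (PBW) from the subject-specific curve.
3. **Classify.** Convert PBWs into binary macrosomia and LGA calls.
4. **Ensemble.** Combine the panel of learners — growth-model variant x
   formula — by majority voting or super-learner stacking, with penalized
   learner selection (LASSO, SCAD or MCP).

Because the motivating Scandinavian cohort is not publicly distributable,
the package ships a calibrated synthetic cohort generator so that every
stage is testable offline.

## Step 1: the formula bank

The 26 formulas live in `inst/extdata/efw_formulas.json` (coefficients in
data, not code). Functional families span log10-linear, natural-log, and
power/volumetric forms; biometry enters in cm, EFW leaves in grams, and
the package applies mm→cm conversion internally so the user-facing unit
is always mm. Two derived measures are computed identically wherever a
formula demands them:

* abdominal circumference `AC = 3.1416 * MAD` — the rounded constant of
  sonographic practice, kept literally rather than replaced by `pi`;
* head circumference from BPD through a configurable linear rule,
  default `HC = 3.58 * BPD` (the perimeter of an ellipse with cephalic
  index 0.78). The original HC source formula is not fully specified in
  the motivating work, so the rule is a documented plug-in
  (`options(fetalens.hc.coef = )`).

Several coefficient sets were transcribed from secondary compilations of
the weight-estimation literature; those entries are flagged with a
`note` in the data file and should be re-verified against their original
articles before any clinical use.

## Step 2: the growth models

Two models are fitted per formula, each with and without baseline
covariates (maternal age, BMI, smoking level, disease-history
indicators), giving the 4 x 26 = 104 learner design:

* the three-parameter **logistic NLME**
  \( y_{ij} = \dfrac{\phi_{1i}}{1 + \exp[-(t_{ij}-\phi_{2i})/\phi_{3i}]} + \varepsilon_{ij} \)
  with \(\phi_{1i} = x_i'\beta_1 + b_{1i}\), \(\phi_{2i} = \beta_2 + b_{2i}\),
  \(\phi_{3i} = \beta_3 + b_{3i}\);
* the **quadratic LME**
  \( y_{ij} = x_i'\beta + \theta_1 t_{ij} + \theta_2 t_{ij}^2
     + b_{0i} + b_{1i} t_{ij} + b_{2i} t_{ij}^2 + \varepsilon_{ij} \).

In both, \(b_i \sim \mathrm{MVN}(0, \Sigma)\) with \(\Sigma\)
unstructured, and the within-subject errors are heteroscedastic with
power-of-the-mean variance \(\mathrm{Var}(\varepsilon_{ij}) =
\sigma^2 |\mu_{ij}|^{2\delta}\). Covariates enter only the amplitude /
level, matching the study configuration. Time is measured in days
throughout; the quadratic model internally centres and scales time
(`ts = (t - 210)/35`) for conditioning.

### Estimation

The default engine is the package's own Lindstrom–Bates-style
alternation (`R/lbfit.R`), chosen so that the thousands of fits inside
cross-validated ensembles run in fractions of a second:

* **Modes.** Per-subject empirical-Bayes modes solve the penalized
  weighted Gauss–Newton problem; the 3x3 per-subject systems are solved
  vectorized across all subjects, with per-subject step halving.
* **Fixed effects.** A marginal GLS step on the linearized working
  response (covariance \(V_i = J_i \Sigma J_i' + R_i\), inverted via the
  Woodbury identity through the same stacked 3x3 curvatures).
* **Variances.** \(\Sigma\) by an EM/Laplace update
  \(\Sigma \leftarrow n^{-1}\sum_i (\hat b_i\hat b_i' + M_i^{-1})\);
  \((\sigma^2, \delta)\) by profiling, with \(\delta\) bounded to
  \([0, 3]\) and the conditional residuals corrected by the EM trace term
  \(J' M^{-1} J\) (without which \(\sigma^2\) is computed from shrunken
  residuals and is biased low).
* **Convergence.** Relative change in the Laplace log-likelihood below
  `1e-8`, or 200 outer iterations; a step-halving safeguard keeps the
  reported log-likelihood non-decreasing, and a plateau rule ends fits
  whose gains fall below `1e-6` three iterations running.
* **Starting values.** Amplitude from 1.1 x the median per-subject
  maximum response; midpoint and stretch from the pooled curve's
  half-maximum and quartile crossings; \(\delta\) starts at 0.5.

`engine = "nlme"` fits the identical models through `nlme::nlme()` /
`nlme::lme()` with a `varPower` variance function; the test suite uses it
as an independent cross-check of the default engine. Options
`delta_fixed` and `ranef_diag` fix the variance exponent and constrain
\(\Sigma\) to diagonal — both are standard simulation-study
simplifications and are markedly faster.

### The evaluation protocol

Learners are fitted once on the training rows *plus the test subjects'
ultrasound rows with the test birth weights masked*: held-out subjects
contribute their scans (so they receive empirical-Bayes modes and hence
predictions) but never their outcome. A dedicated test poisons the
held-out birth weights and asserts that no training-subject prediction
moves.

## Step 3: classification rules

* **Macrosomia**: PBW strictly above 4000 g ("more than" is taken
  literally, so exactly 4000 g is negative).
* **LGA**: subject *i* is positive when its PBW at its own delivery time
  \(T_i\) strictly exceeds the 90th percentile of *all other* subjects'
  predicted weights evaluated at that same \(T_i\) — a counterfactual
  "everyone born at \(T_i\)" comparison, which is why the growth models
  must predict at arbitrary times. The percentile is the
  linear-interpolation sample quantile (R type 7); the reference
  population defaults to all subjects in the panel and is configurable.

## Step 4: ensembles

* **Voting** assigns the class with strictly more than half of the
  selected learners' votes (a tie is negative); the positive-vote
  fraction serves as the graded score for ROC analysis. Voters are
  selected by a penalized logistic regression of the training truth on
  the learners' binary predictions; learners with nonzero coefficients at
  the cross-validated lambda are kept, and an empty selection falls back
  to all learners with a warning.
* **Stacking** trains a second-level meta-learner on the "leave-one
  data": K-fold (default 10) cross-validation inside the training set,
  refitting every first-level learner per fold with the held-out fold's
  birth weights masked. For macrosomia the meta features are the
  cross-validated *continuous* PBWs and the meta-learner is a linear
  regression of observed birth weight (which is why a linear meta-learner
  is the natural choice there), final label = meta-prediction > 4000 g;
  for LGA the features are the cross-validated *binary* flags and the
  meta-learner is a positivity-constrained logistic regression (or a
  penalized one when a selector is requested), final label =
  probability > 0.5. The feature-type split is a documented design
  choice; the motivating description names the meta-learner families but
  not their inputs.

## The penalized solvers

LASSO, SCAD (shape `a = 3.7`) and MCP (shape `gamma = 3`) are solved by
coordinate descent with exact univariate threshold operators — including
the global candidate comparison needed when the IRLS curvature is too
small for the folded-concave branch to stay convex — over a 100-value
log-spaced path from `lambda_max` down to `0.001 * lambda_max`, with
lambda chosen by stratified K-fold cross-validated deviance (minimum
rule, not 1-SE). Folded-concave solves warm-start from the lasso path.
The compiled core (`src/cd.cpp`) guards against separation chasing: IRLS
stops once fitted probabilities saturate, and the path exits early when
the deviance is essentially exhausted. Ensemble-level *selection* fits
use a 50-value path stopped at `0.01 * lambda_max`: the learner-vote
features are near-separating and the deep tail is degenerate there — the
CV minimum never falls in it.

The positivity-constrained logistic meta-learner maximizes the
likelihood under box constraints (L-BFGS-B) and reports its maximal KKT
violation.

## Diagnostic metrics

AUC is the Mann–Whitney probability with ties at half credit, with
DeLong 95% intervals (via pROC); sensitivity, specificity and predictive
values carry exact Clopper–Pearson intervals; likelihood ratios use the
standard log-method interval. The published comparison tables report CIs
without naming their methods, so these are the package's documented
choices. Youden's index is always `sensitivity + specificity - 1` and is
asserted to machine precision on every report.

## The synthetic cohort

`simulate_cohort()` draws covariates from independent marginals
calibrated to the published cohort description (maternal age 28.3 ± 4.1
years, height 166 ± 6 cm, weight 59 ± 10 kg, smoking categories from
the printed counts, disease indicators at their printed prevalences;
correlations are not modelled because none are published). Trajectories
are logistic with amplitude intercept set so the mean birth weight at
280 d is 3562 g; the random-effect SDs (470 g, 5 d, 1.5 d with a 0.2
amplitude–midpoint correlation), the gestational-age SD 8.34 d and the
residual scale (sigma = 2.85, delta = 0.5) were budgeted so the marginal
birth-weight SD is ~478 g and macrosomia prevalence lands near 17.5%.
LGA prevalence near 10% follows from the percentile rule by
construction.

Visit biometry is produced by *inverting* formula 1 of the bank against
the true trajectory weight under gestational-age-dependent reference
proportions (monotone splines through chart-typical anchors), then
adding measurement noise (SD 1 / 1.5 / 1 mm for BPD / MAD / FL). This
keeps the EFW–biometry relation self-consistent — re-applying formula 1
recovers the generating weight exactly up to the injected noise — and is
one admissible choice; the motivating study never describes biometry
trajectories. Weights below a formula's attainable floor (possible only
in extreme early-gestation tails) are clamped just above it.

What the generator does *not* emulate: 1980s ultrasound device error
structure, covariate correlations, the original risk-stratified sampling
design, or independent error sources per formula. The last point
matters for interpreting the ensemble study below: all learners see the
same single biometry-noise realization, so learner errors are more
correlated here than across genuinely different measurement pipelines.

## The simulation studies and their outcomes

Problem sizes are the package's standing choices: the recovery study
fits each model to 20 cohorts of n = 500 simulated at known parameters;
the ensemble study runs 20 replicates at n = 300 with learners =
{logistic, quadratic} x formulas 1–6 (no covariates), a 70/30 split
stratified by macrosomia, K = 3 leave-one folds and 5-fold selection CV.

Two honest limitations surface there, both reproducible via
`recovery_study()` and `ensemble_study()`:

* **Logistic Wald coverage.** Fixed-effect bias is well under 5% for
  both models, and quadratic-LME coverage is nominal, but the logistic
  NLME's Laplace/Lindstrom–Bates estimator carries a small systematic
  bias (amplitude about -1.2%) that is roughly twice its standard error
  at n = 500, so its Wald intervals under-cover (~40–60%). An exact
  maximum-likelihood oracle on a reduced model is unbiased, and
  `nlme::nlme` shows the same bias on identical data: this is a property
  of the approximation family, which decays with per-subject series
  length (five observations here), not with the number of subjects.
  Adaptive quadrature would remove it but is deliberately out of scope.
* **Voting versus the best learner.** Stacking with SCAD or MCP
  selection beats the strongest individual learner on average (mean
  held-out Youden 0.63 vs 0.55); voting with selection does not (~0.51),
  because the synthetic learners' errors are strongly correlated (shared
  noise realization, two curve families), so majority voting cannot
  denoise and extra voters only dilute the best one. The stacking half
  of the qualitative claim — selective ensembles outperform any single
  formula-model pair — reproduces cleanly.

## Reproducibility

Every stochastic step takes an explicit integer seed, and the pipeline
is deterministic given one (`run_full_pipeline()` twice with the same
seed is byte-identical). The numbered drivers under `analysis/` re-run
the full narrative; `scripts/acceptance.R` recomputes the headline
quantities from scratch and writes them as JSON.
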