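#' Simulate longitudinal data directly from a growth model
#'
#' Draws per-subject series straight from the logistic or quadratic
#' mixed-effects model at known parameter values — the generating truth for
#' parameter-recovery studies. Unlike [simulate_cohort()] there is no
#' EFW-formula layer: the response is the model mean plus power-variance
#' noise. Four ultrasound-style visits plus a delivery time mimic the
#' cohort design.
#'
#' @param model `"logistic"` or `"quadratic"`.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param beta Length-3 fixed effects: logistic `(amplitude, midpoint,
#'   stretch)`; quadratic `(level, slope, curvature)` on the internal
#'   `ts = (t - 210)/35` scale.
#' @param sds Random-effect standard deviations (length 3).
#' @param corr12 Correlation between the first two random effects.
#' @param sigma,delta Residual scale and variance-power exponent.
#' @return Data frame `id` (factor), `t` (days), `y` (grams).
#' @export
simulate_growth_data <- function(model = c("logistic", "quadratic"),
                                 n, seed,
                                 beta = NULL,
                                 sds = NULL, corr12 = NULL,
                                 sigma = 2.85, delta = 0.5) {
  model <- match.arg(model)
  if (is.null(beta)) {
    beta <- if (model == "logistic") c(4210, 234, 27) else c(1300, 1000, 200)
  }
  if (is.null(sds)) {
    sds <- if (model == "logistic") c(470, 5, 1.5) else c(300, 60, 25)
  }
  if (is.null(corr12)) corr12 <- if (model == "logistic") 0.2 else 0.3
  set.seed(seed)
  corr <- diag(3); corr[1, 2] <- corr[2, 1] <- corr12
  Sig <- diag(sds) %*% corr %*% diag(sds)
  b <- MASS::mvrnorm(n, rep(0, 3), Sig)
  tvis <- c(119, 175, 231, 259)
  birth <- round(stats::rnorm(n, 280, 8.34))
  dat <- do.call(rbind, lapply(seq_len(n), function(i) {
    tt <- c(tvis + round(stats::rnorm(4, 0, 3)), birth[i])
    mu <- if (model == "logistic") {
      (beta[1] + b[i, 1]) /
        (1 + exp(-(tt - beta[2] - b[i, 2]) / (beta[3] + b[i, 3])))
    } else {
      ts <- (tt - 210) / 35
      (beta[1] + b[i, 1]) + (beta[2] + b[i, 2]) * ts +
        (beta[3] + b[i, 3]) * ts^2
    }
    data.frame(id = i, t = tt,
               y = mu + stats::rnorm(5, 0, sigma * pmax(abs(mu), 1)^delta))
  }))
  dat$id <- factor(dat$id)
  attr(dat, "truth") <- list(beta = beta, Sigma = Sig, sigma = sigma,
                             delta = delta)
  dat
}

# wrap raw (id, t, y) rows into the cohort+efw surface of fit_growth_model,
# with inert covariates (the recovery studies fit without covariates)
.rows_as_cohort <- function(dat) {
  birth_idx <- unlist(tapply(seq_len(nrow(dat)), dat$id,
                             function(k) k[which.max(dat$t[k])]))
  ids <- levels(dat$id)
  subjects <- data.frame(id = ids, age = 28, bmi = 21.5, smoking = 1,
                         hbp = 0, cardiac = 0, diabetes = 0, renal = 0,
                         other_disease = 0,
                         birth_ga = dat$t[birth_idx],
                         birth_weight = dat$y[birth_idx])
  subjects$age[1] <- 29 # keep every covariate non-constant
  efw_rows <- dat[-birth_idx, ]
  list(cohort = structure(list(subjects = subjects,
                               visits = data.frame(id = efw_rows$id,
                                                   t = efw_rows$t)),
                          class = "fetal_cohort"),
       efw = data.frame(id = as.character(efw_rows$id), t = efw_rows$t,
                        efw = efw_rows$y))
}

#' Fixed-effect recovery study for one growth model
#'
#' Repeatedly simulates cohorts from known parameters with
#' [simulate_growth_data()], refits the model, and summarizes the relative
#' bias of the fixed effects and the empirical coverage of their 95% Wald
#' intervals.
#'
#' @param model `"logistic"` or `"quadratic"`.
#' @param n Subjects per replicate (default 500).
#' @param n_reps Number of replicates (default 20).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List with `estimates` (replicates x 3), `se`, `truth`,
#'   `bias_pct` (mean relative bias, percent), `coverage`.
#' @export
recovery_study <- function(model = c("logistic", "quadratic"),
                           n = 500, n_reps = 20, seed = 1L) {
  model <- match.arg(model)
  est <- se <- matrix(NA_real_, n_reps, 3)
  truth <- NULL
  for (r in seq_len(n_reps)) {
    dat <- simulate_growth_data(model, n, seed = seed + r)
    truth <- attr(dat, "truth")$beta
    w <- .rows_as_cohort(dat)
    fit <- suppressWarnings(fit_growth_model(w$cohort, w$efw, model))
    est[r, ] <- if (model == "logistic") {
      c(fit$beta1[1], fit$beta2, fit$beta3)
    } else {
      c(fit$beta[1], fit$theta1, fit$theta2)
    }
    se[r, ] <- fit$beta_se[c(1, length(fit$beta_se) - 1,
                             length(fit$beta_se))]
  }
  bias_pct <- 100 * (colMeans(est) - truth) / truth
  coverage <- vapply(1:3, function(k) {
    mean(abs(est[, k] - truth[k]) <= stats::qnorm(0.975) * se[, k])
  }, numeric(1))
  list(estimates = est, se = se, truth = truth,
       bias_pct = bias_pct, coverage = coverage)
}

#' Scaled ensemble-versus-best-learner simulation study
#'
#' The package's reproduction, at desk scale, of the central empirical
#' claim: on cohorts with redundant and noisy learners, ensembles with
#' folded-concave learner selection compete with the strongest individual
#' learner. Each replicate simulates a cohort, splits 70/30 stratified by
#' macrosomia, fits the learner set (logistic and quadratic growth models
#' crossed with a formula subset, no covariates), and evaluates on the
#' held-out subjects: every individual learner's Youden index plus
#' majority voting and stacking with SCAD and MCP selection.
#'
#' @param n_reps Number of replicates (default 20).
#' @param n_subjects Cohort size per replicate (default 300).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param formula_ids EFW formulas for the learner grid (default 1:6).
#' @param K Leave-one-data folds for stacking (default 3).
#' @param n_folds CV folds for the penalized selection fits (default 5).
#' @return List with `youden` (replicates x outcomes matrix), `means`,
#'   `best_individual` (name and mean of the strongest learner),
#'   `ensemble_means`.
#' @export
ensemble_study <- function(n_reps = 20, n_subjects = 300, seed = 1L,
                           formula_ids = 1:6, K = 3, n_folds = 5) {
  out <- NULL
  grid <- learner_grid(models = data.frame(model = c("logistic", "quadratic"),
                                           with_covariates = FALSE),
                       formula_ids = formula_ids)
  for (r in seq_len(n_reps)) {
    rep_seed <- seed + r
    co <- simulate_cohort(sim_config(n_subjects = n_subjects,
                                     seed = rep_seed))
    s <- co$subjects
    sp <- stratified_split(s$id, 0.7, s$macrosomia, seed = rep_seed)
    fits <- suppressWarnings(fit_learners(co, grid,
                                          mask_birth_ids = sp$test))
    panel <- suppressMessages(
      build_learner_panel(co, fits, targets = "macrosomia"))
    ptr <- panel_subset(panel, sp$train)
    pte <- panel_subset(panel, sp$test)
    ytr <- s$macrosomia[match(sp$train, s$id)]
    yte <- s$macrosomia[match(sp$test, s$id)]
    row <- vapply(panel$learners, function(ln) {
      rates(confusion(pte$macro[, ln], yte))$youden
    }, numeric(1))
    meta <- suppressWarnings(
      build_leave_one_data(co, grid, sp$train, "macrosomia", K = K,
                           seed = rep_seed))
    for (sel in c("scad", "mcp")) {
      v <- suppressWarnings(fit_voting(ptr, ytr, "macrosomia",
                                       selector = sel, seed = rep_seed,
                                       n_folds = n_folds))
      row[paste0("voting_", sel)] <-
        rates(confusion(predict_ensemble(v, pte)$label, yte))$youden
      st <- suppressWarnings(fit_stacking(meta, selector = sel,
                                          seed = rep_seed,
                                          n_folds = n_folds))
      row[paste0("stacking_", sel)] <-
        rates(confusion(predict_ensemble(st, pte)$label, yte))$youden
    }
    out <- rbind(out, row)
  }
  means <- colMeans(out)
  ind <- means[!grepl("voting_|stacking_", names(means))]
  list(youden = out, means = means,
       best_individual = ind[which.max(ind)],
       ensemble_means = means[grepl("voting_|stacking_", names(means))])
}
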