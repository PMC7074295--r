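#' Fit a mixed-effects fetal growth model
#'
#' Fits one of the two subject-specific growth models to the stacked
#' response of estimated fetal weights at the ultrasound visits plus the
#' observed birth weight at delivery:
#'
#' * `"logistic"`: the three-parameter logistic nonlinear mixed-effects
#'   model `y_ij = phi1_i / (1 + exp(-(t_ij - phi2_i)/phi3_i)) + e_ij` with
#'   `phi1_i = x_i' beta1 + b1_i`, `phi2_i = beta2 + b2_i`,
#'   `phi3_i = beta3 + b3_i`, random effects `b_i ~ MVN(0, Sigma)`
#'   (unstructured), and heteroscedastic within-subject errors
#'   `Var(e_ij) = sigma^2 |mu_ij|^(2*delta)` (power-of-the-mean variance).
#'   Estimated by the Lindstrom-Bates alternating algorithm
#'   (Laplace-approximate marginal likelihood) as implemented in
#'   [nlme::nlme()] with a `varPower` variance function.
#' * `"quadratic"`: the linear mixed-effects model
#'   `y_ij = x_i' beta + theta1 t_ij + theta2 t_ij^2 + b0_i + b1_i t_ij +
#'   b2_i t_ij^2 + e_ij` with the same error configuration, via
#'   [nlme::lme()] (time is internally centred and scaled for numerical
#'   stability; reported `theta` are on the internal scale, predictions are
#'   on the original scale).
#'
#' Baseline covariates (see [model_covariates()]) enter only the amplitude
#' `phi1_i` (logistic) or `x_i' beta` (quadratic) when
#' `with_covariates = TRUE`.
#'
#' Subjects listed in `mask_birth_ids` contribute only their ultrasound
#' rows: their birth weights are never read by the fit, yet they still
#' receive empirical-Bayes random-effect modes and hence predictions. This
#' is the evaluation protocol for held-out subjects.
#'
#' @param cohort A `fetal_cohort` (or a list with `subjects` and `visits`
#'   data frames of the same shape).
#' @param efw Data frame `id`, `t`, `efw` from [efw_records()] — the
#'   visit-level responses under one EFW formula.
#' @param model `"logistic"` or `"quadratic"`.
#' @param with_covariates Include baseline covariates in the amplitude/mean.
#' @param mask_birth_ids Ids whose birth weights must not enter the fit.
#' @param heteroscedastic Use the power-variance error model (default TRUE).
#' @param delta_fixed Optionally fix the variance exponent delta at a known
#'   value instead of profiling it (appreciably faster; used by the
#'   scaled-down simulation studies where delta is known by construction).
#' @param ranef_diag Constrain the random-effect covariance to diagonal
#'   (much faster; the default keeps Sigma unstructured).
#' @param engine `"lb"` (default) for the package's vectorized
#'   Lindstrom-Bates/Laplace alternation, or `"nlme"` to fit through
#'   [nlme::nlme()] / [nlme::lme()] (slower; used as an independent
#'   cross-check).
#' @return An object of class `"growth_fit"`: fixed effects, `Sigma`,
#'   `delta`, `sigma2`, per-subject empirical-Bayes coefficient table,
#'   log-likelihood and a convergence flag.
#' @export
fit_growth_model <- function(cohort, efw,
                             model = c("logistic", "quadratic"),
                             with_covariates = FALSE,
                             mask_birth_ids = NULL,
                             heteroscedastic = TRUE,
                             delta_fixed = NULL,
                             ranef_diag = FALSE,
                             engine = c("lb", "nlme")) {
  model <- match.arg(model)
  engine <- match.arg(engine)
  subjects <- cohort$subjects
  keep_birth <- !(subjects$id %in% mask_birth_ids)
  birth_rows <- data.frame(id = subjects$id[keep_birth],
                           t = subjects$birth_ga[keep_birth],
                           y = subjects$birth_weight[keep_birth])
  dat <- rbind(data.frame(id = efw$id, t = efw$t, y = efw$efw), birth_rows)
  dat <- dat[order(dat$id, dat$t), ]
  if (min(table(dat$id)) < 2) stop("every subject needs at least 2 time points")

  covs <- model_covariates()
  # a rare binary covariate can be constant in a small cohort; keep the
  # design nonsingular
  covs <- covs[vapply(subjects[covs], function(v) stats::sd(v) > 0,
                      logical(1))]
  centers <- colMeans(subjects[covs])
  Xc <- sweep(as.matrix(subjects[covs]), 2, centers)
  rownames(Xc) <- subjects$id
  if (with_covariates) {
    dat <- cbind(dat, as.data.frame(Xc[match(dat$id, subjects$id), ]))
  }
  dat$id <- factor(dat$id)

  fit <- if (engine == "lb") {
    .fit_lb_wrap(dat, subjects, Xc, covs, model, with_covariates,
                 heteroscedastic, delta_fixed, ranef_diag)
  } else if (model == "logistic") {
    .fit_logistic_nlme(dat, covs, with_covariates, heteroscedastic,
                       delta_fixed, ranef_diag)
  } else {
    .fit_quadratic_lme(dat, covs, with_covariates, heteroscedastic,
                       delta_fixed, ranef_diag)
  }
  fit$engine <- engine
  fit$model <- model
  fit$with_covariates <- with_covariates
  fit$covariate_centers <- centers
  fit$subject_ids <- as.character(subjects$id)
  class(fit) <- "growth_fit"
  fit
}

# starting values per the pooled-curve heuristics: amplitude from 1.1 x the
# median per-subject maximum, midpoint from the pooled half-maximum
# crossing, stretch from the pooled quartile crossings of the curve
.logistic_starts <- function(t, y, id) {
  A0 <- 1.1 * stats::median(tapply(y, id, max))
  wk <- round(t / 7)
  curve <- tapply(y, wk, mean)
  tt <- as.numeric(names(curve)) * 7
  cross <- function(frac) {
    target <- frac * A0
    above <- which(curve >= target)
    if (length(above) == 0 || above[1] == 1) return(NA_real_)
    k <- above[1]
    tt[k - 1] + (target - curve[k - 1]) / (curve[k] - curve[k - 1]) *
      (tt[k] - tt[k - 1])
  }
  m0 <- unname(cross(0.5))
  t25 <- cross(0.25); t75 <- cross(0.75)
  s0 <- if (is.finite(t25) && is.finite(t75)) (t75 - t25) / (2 * log(3)) else 25
  if (!is.finite(m0)) m0 <- stats::median(t)
  c(A = unname(A0), m = m0, s = unname(max(s0, 5)))
}

.fit_logistic_nlme <- function(dat, covs, with_covariates, heteroscedastic,
                               delta_fixed = NULL, ranef_diag = FALSE) {
  st <- .logistic_starts(dat$t, dat$y, dat$id)
  if (with_covariates) {
    fixed <- eval(parse(text = paste0(
      "list(A ~ ", paste(covs, collapse = " + "), ", m ~ 1, s ~ 1)")))
    start <- c(st[["A"]], rep(0, length(covs)), st[["m"]], st[["s"]])
  } else {
    fixed <- A + m + s ~ 1
    start <- st
  }
  ctrl <- nlme::nlmeControl(maxIter = 200, msMaxIter = 200, pnlsMaxIter = 15,
                            returnObject = TRUE)
  attempt <- function(random) {
    # the varFunc object is mutated in place by nlme: build it per call
    wts <- if (!heteroscedastic) NULL
           else if (is.null(delta_fixed)) nlme::varPower(form = ~fitted(.))
           else nlme::varPower(form = ~fitted(.), fixed = delta_fixed)
    nlme::nlme(y ~ A / (1 + exp(-(t - m) / s)), data = dat, fixed = fixed,
               random = random, groups = ~id, start = start,
               weights = wts, method = "ML", control = ctrl)
  }
  warned <- character()
  catch_warn <- function(w) {
    warned <<- c(warned, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  ranef_structure <- if (ranef_diag) "diagonal" else "unstructured"
  fit <- if (ranef_diag) {
    tryCatch(withCallingHandlers(attempt(nlme::pdDiag(A + m + s ~ 1)),
                                 warning = catch_warn),
             error = function(e) {
               stop("logistic growth model failed to fit: ",
                    conditionMessage(e))
             })
  } else tryCatch(
    withCallingHandlers(attempt(A + m + s ~ 1), # pdLogChol, unstructured
                        warning = catch_warn),
    error = function(e1) {
      ranef_structure <<- "diagonal"
      tryCatch(withCallingHandlers(attempt(nlme::pdDiag(A + m + s ~ 1)),
                                   warning = catch_warn),
               error = function(e2) {
                 stop("logistic growth model failed to fit: ",
                      conditionMessage(e2))
               })
    })
  converged <- !any(grepl("[Ii]teration|[Cc]onverg", warned))

  fe <- nlme::fixef(fit)
  nA <- if (with_covariates) 1 + length(covs) else 1
  re <- nlme::ranef(fit)
  # per-subject curve parameters from fixed effects + empirical-Bayes modes
  ids <- rownames(re)
  if (with_covariates) {
    Xfit <- unique(dat[c("id", covs)])
    X <- cbind(1, as.matrix(Xfit[match(ids, as.character(Xfit$id)), covs]))
    A_fix <- drop(X %*% fe[seq_len(nA)])
  } else {
    A_fix <- rep(fe[["A"]], length(ids))
  }
  phi <- data.frame(
    id = ids,
    phi1 = A_fix + re$A,
    phi2 = fe[[nA + 1]] + re$m,
    phi3 = fe[[nA + 2]] + re$s
  )
  delta <- if (!heteroscedastic) 0
           else if (!is.null(delta_fixed)) delta_fixed
           else as.numeric(stats::coef(fit$modelStruct$varStruct,
                                       uncons = FALSE))
  Sigma <- tryCatch(
    nlme::pdMatrix(fit$modelStruct$reStruct[[1]]) * fit$sigma^2,
    error = function(e) matrix(NA_real_, 3, 3))
  list(engine_fit = fit,
       beta1 = fe[seq_len(nA)], beta2 = fe[[nA + 1]], beta3 = fe[[nA + 2]],
       Sigma = Sigma, delta = delta, sigma2 = fit$sigma^2,
       phi = phi, loglik = as.numeric(stats::logLik(fit)),
       converged = converged, ranef_structure = ranef_structure)
}

.fit_quadratic_lme <- function(dat, covs, with_covariates, heteroscedastic,
                               delta_fixed = NULL, ranef_diag = FALSE) {
  t_center <- 210; t_scale <- 35
  dat$ts <- (dat$t - t_center) / t_scale
  form <- if (with_covariates) {
    stats::as.formula(paste("y ~", paste(covs, collapse = " + "),
                            "+ ts + I(ts^2)"))
  } else y ~ ts + I(ts^2)
  ctrl <- nlme::lmeControl(maxIter = 200, msMaxIter = 200,
                           returnObject = TRUE)
  mk_wts <- function() {
    if (!heteroscedastic) NULL
    else if (is.null(delta_fixed)) nlme::varPower(form = ~fitted(.))
    else nlme::varPower(form = ~fitted(.), fixed = delta_fixed)
  }
  warned <- character()
  catch_warn <- function(w) {
    warned <<- c(warned, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  ranef_structure <- if (ranef_diag) "diagonal" else "unstructured"
  fit <- if (ranef_diag) {
    withCallingHandlers(nlme::lme(form, data = dat,
                                  random = list(id = nlme::pdDiag(~ ts + I(ts^2))),
                                  weights = mk_wts(), method = "ML",
                                  control = ctrl),
                        warning = catch_warn)
  } else tryCatch(
    withCallingHandlers(nlme::lme(form, data = dat,
                                  random = ~ ts + I(ts^2) | id,
                                  weights = mk_wts(), method = "ML",
                                  control = ctrl),
                        warning = catch_warn),
    error = function(e1) {
      ranef_structure <<- "diagonal"
      withCallingHandlers(nlme::lme(form, data = dat,
                                    random = nlme::pdDiag(~ ts + I(ts^2)),
                                    weights = mk_wts(), method = "ML",
                                    control = ctrl),
                          warning = catch_warn)
    })
  converged <- !any(grepl("[Ii]teration|[Cc]onverg", warned))
  fe <- nlme::fixef(fit)
  re <- nlme::ranef(fit)
  ids <- rownames(re)
  if (with_covariates) {
    Xfit <- unique(dat[c("id", covs)])
    X <- as.matrix(Xfit[match(ids, as.character(Xfit$id)), covs])
    base <- fe[["(Intercept)"]] + drop(X %*% fe[covs])
  } else {
    base <- rep(fe[["(Intercept)"]], length(ids))
  }
  coefs <- data.frame(
    id = ids,
    a0 = base + re[["(Intercept)"]],
    a1 = fe[["ts"]] + re[["ts"]],
    a2 = fe[["I(ts^2)"]] + re[["I(ts^2)"]]
  )
  delta <- if (!heteroscedastic) 0
           else if (!is.null(delta_fixed)) delta_fixed
           else as.numeric(stats::coef(fit$modelStruct$varStruct,
                                       uncons = FALSE))
  Sigma <- tryCatch(
    nlme::pdMatrix(fit$modelStruct$reStruct[[1]]) * fit$sigma^2,
    error = function(e) matrix(NA_real_, 3, 3))
  list(engine_fit = fit,
       beta = fe[setdiff(names(fe), c("ts", "I(ts^2)"))],
       theta1 = fe[["ts"]], theta2 = fe[["I(ts^2)"]],
       Sigma = Sigma, delta = delta, sigma2 = fit$sigma^2,
       coefs = coefs, t_center = t_center, t_scale = t_scale,
       loglik = as.numeric(stats::logLik(fit)), converged = converged,
       ranef_structure = ranef_structure)
}

#' Predict subject-specific weight at an arbitrary time
#'
#' Plugs the subject's empirical-Bayes coefficient modes into the fitted
#' subject-specific mean function. Defined for any time, not only the
#' subject's own observation times — the LGA rule needs predictions for
#' every fetus at another fetus's delivery time.
#'
#' @param fit A `growth_fit`.
#' @param ids Subject id(s), recycled against `t`.
#' @param t Gestational age(s) in days.
#' @return Predicted weight(s) in grams.
#' @export
predict_weight <- function(fit, ids, t) {
  ids <- as.character(ids)
  if (fit$model == "logistic") {
    k <- match(ids, fit$phi$id)
    if (any(is.na(k))) stop("unknown subject id(s): ",
                            paste(unique(ids[is.na(k)]), collapse = ", "))
    fit$phi$phi1[k] / (1 + exp(-(t - fit$phi$phi2[k]) / fit$phi$phi3[k]))
  } else {
    k <- match(ids, fit$coefs$id)
    if (any(is.na(k))) stop("unknown subject id(s): ",
                            paste(unique(ids[is.na(k)]), collapse = ", "))
    ts <- (t - fit$t_center) / fit$t_scale
    fit$coefs$a0[k] + fit$coefs$a1[k] * ts + fit$coefs$a2[k] * ts^2
  }
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> ", x$model,
      if (x$with_covariates) " + covariates" else "",
      "; subjects: ", length(x$subject_ids),
      "; delta = ", signif(x$delta, 3),
      "; logLik = ", signif(x$loglik, 6),
      if (!x$converged) "  [convergence fallback]" else "", "\n", sep = "")
  invisible(x)
}


# adapter from the Lindstrom-Bates core to the growth_fit surface
.fit_lb_wrap <- function(dat, subjects, Xc, covs, model, with_covariates,
                         heteroscedastic, delta_fixed, ranef_diag) {
  ids <- levels(dat$id)
  ord <- match(ids, as.character(subjects$id))
  X <- if (with_covariates) {
    cbind(1, Xc[ord, , drop = FALSE])
  } else {
    matrix(1, length(ids), 1)
  }
  core <- .lb_fit(dat, X, model, heteroscedastic, delta_fixed, ranef_diag)
  q <- core$q
  amp <- drop(X %*% core$beta[seq_len(q)]) + core$b[, 1]
  se <- sqrt(pmax(diag(core$beta_cov), 0))
  bnames <- c("(Intercept)", if (with_covariates) covs,
              if (model == "logistic") c("m", "s") else c("ts", "I(ts^2)"))
  names(se) <- bnames
  out <- list(
    Sigma = core$Sigma, delta = core$delta, sigma2 = core$sigma2,
    loglik = core$loglik, loglik_trace = core$loglik_trace,
    converged = core$converged, beta_se = se, beta_cov = core$beta_cov,
    ranef_structure = if (ranef_diag) "diagonal" else "unstructured",
    ranef_modes = core$b
  )
  if (model == "logistic") {
    out$beta1 <- stats::setNames(core$beta[seq_len(q)], bnames[seq_len(q)])
    out$beta2 <- core$beta[q + 1]
    out$beta3 <- core$beta[q + 2]
    out$phi <- data.frame(id = ids, phi1 = amp,
                          phi2 = core$beta[q + 1] + core$b[, 2],
                          phi3 = core$beta[q + 2] + core$b[, 3])
  } else {
    out$beta <- stats::setNames(core$beta[seq_len(q)], bnames[seq_len(q)])
    out$theta1 <- core$beta[q + 1]
    out$theta2 <- core$beta[q + 2]
    out$t_center <- 210
    out$t_scale <- 35
    out$coefs <- data.frame(id = ids, a0 = amp,
                            a1 = core$beta[q + 1] + core$b[, 2],
                            a2 = core$beta[q + 2] + core$b[, 3])
  }
  out
}
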