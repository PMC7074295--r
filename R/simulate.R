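#' Configuration for the synthetic cohort generator
#'
#' Assembles and validates the parameters of the synthetic longitudinal
#' cohort: a Scandinavian-style birth cohort with four scheduled ultrasound
#' visits (~17, 25, 33, 37 weeks), subject-level covariates, a logistic
#' fetal growth trajectory with trivariate normal random effects, and
#' heteroscedastic power-of-the-mean measurement error. Defaults are
#' calibrated so that birth weight has mean ~3562 g and SD ~478 g,
#' gestational age at delivery mean 280 d and SD 8.34 d, and macrosomia
#' (>4000 g) prevalence close to 17.5%.
#'
#' The trajectory for subject i is
#' `w_i(t) = phi1_i / (1 + exp(-(t - phi2_i)/phi3_i))` with
#' `phi1_i = x_i' beta1 + b1_i`, `phi2_i = beta2 + b2_i`,
#' `phi3_i = beta3 + b3_i`, `b_i ~ MVN(0, Sigma)`. Birth weight is
#' `w_i(T_i) + e`, `sd(e) = sigma * |w_i(T_i)|^delta`. Visit biometry is
#' obtained by inverting the reference EFW formula (see [invert_efw()])
#' against `w_i(t)` and adding measurement noise.
#'
#' @param n_subjects Number of subjects.
#' @param visit_weeks Scheduled ultrasound visits in gestational weeks,
#'   strictly increasing.
#' @param visit_jitter_sd SD of the per-visit timing jitter in days.
#' @param birth_ga_mean,birth_ga_sd Gestational age at delivery, days.
#' @param birthweight_mean Target mean birth weight (g); sets the amplitude
#'   intercept `beta1[1] = birthweight_mean / plogis((birth_ga_mean - beta2)/beta3)`.
#' @param beta2,beta3 Fixed effects for trajectory midpoint (days) and
#'   stretch (days).
#' @param covariate_effects Named vector of amplitude effects (g per unit of
#'   the centred covariate) for `age`, `bmi`, `smoking`, `hbp`, `cardiac`,
#'   `diabetes`, `renal`, `other_disease`.
#' @param ranef_cov 3x3 positive-definite covariance of `(b1, b2, b3)`.
#' @param variance_power Heteroscedasticity exponent delta.
#' @param sigma Residual scale (g^(1-delta)).
#' @param biometry_noise_sd Named vector, measurement SD in mm for
#'   `bpd`, `mad`, `fl`.
#' @param reference_formula Formula id used to invert weight into biometry.
#' @param seed Integer seed driving all randomness.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_subjects = 1115,
                       visit_weeks = c(17, 25, 33, 37),
                       visit_jitter_sd = 3,
                       birth_ga_mean = 280,
                       birth_ga_sd = 8.34,
                       birthweight_mean = 3562,
                       beta2 = 234,
                       beta3 = 27,
                       covariate_effects = c(age = 2, bmi = 8, smoking = -25,
                                             hbp = -60, cardiac = -40,
                                             diabetes = 150, renal = -60,
                                             other_disease = -20),
                       ranef_cov = NULL,
                       variance_power = 0.5,
                       sigma = 2.85,
                       biometry_noise_sd = c(bpd = 1, mad = 1.5, fl = 1),
                       reference_formula = 1L,
                       seed = 20260927L) {
  if (is.null(ranef_cov)) {
    sds <- c(470, 5, 1.5)
    corr <- diag(3)
    corr[1, 2] <- corr[2, 1] <- 0.2
    ranef_cov <- diag(sds) %*% corr %*% diag(sds)
  }
  cfg <- list(n_subjects = n_subjects, visit_weeks = visit_weeks,
              visit_jitter_sd = visit_jitter_sd,
              birth_ga_mean = birth_ga_mean, birth_ga_sd = birth_ga_sd,
              birthweight_mean = birthweight_mean,
              beta2 = beta2, beta3 = beta3,
              covariate_effects = covariate_effects,
              ranef_cov = ranef_cov, variance_power = variance_power,
              sigma = sigma, biometry_noise_sd = biometry_noise_sd,
              reference_formula = reference_formula, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_subjects >= 0,
            all(diff(cfg$visit_weeks) > 0),
            cfg$birth_ga_sd > 0, cfg$visit_jitter_sd >= 0,
            cfg$variance_power >= 0, cfg$sigma >= 0)
  S <- cfg$ranef_cov
  if (!isTRUE(all.equal(S, t(S))) ||
      inherits(try(chol(S + diag(1e-9, 3)), silent = TRUE), "try-error")) {
    stop("`ranef_cov` must be a symmetric positive-definite 3x3 matrix")
  }
  invisible(cfg)
}

# Table-1-calibrated covariate marginals (independent sampling; the source
# table reports no correlations). Smoking categories use the printed counts
# 436/180/397/102 (cigarettes/day 0, 1-9, 10-19, 20+).
.draw_covariates <- function(n) {
  age <- stats::rnorm(n, 28.32, 4.12)
  height <- stats::rnorm(n, 165.96, 5.99)
  weight <- stats::rnorm(n, 59.20, 10.00)
  bmi <- weight / (height / 100)^2
  data.frame(
    age = age, height = height, weight = weight, bmi = bmi,
    parity = sample(1:2, n, replace = TRUE),
    smoking = sample(0:3, n, replace = TRUE,
                     prob = c(436, 180, 397, 102) / 1115),
    hbp = stats::rbinom(n, 1, 0.018),
    cardiac = stats::rbinom(n, 1, 0.009),
    diabetes = stats::rbinom(n, 1, 0.003),
    renal = stats::rbinom(n, 1, 0.010),
    other_disease = stats::rbinom(n, 1, 0.154)
  )
}

#' Covariate names entering the growth models
#' @return Character vector of the modelled baseline covariates.
#' @export
model_covariates <- function() {
  c("age", "bmi", "smoking", "hbp", "cardiac", "diabetes", "renal",
    "other_disease")
}

#' Simulate a longitudinal ultrasound cohort
#'
#' Draws a complete synthetic cohort under the generative model described
#' in [sim_config()]: covariates, subject-specific logistic growth
#' trajectories, gestational age at delivery, birth weight with
#' heteroscedastic error, and per-visit biometry (BPD, MAD, FL) obtained by
#' inverting the reference EFW formula against the true trajectory plus
#' measurement noise. True trajectory parameters are kept in the
#' `"truth"` attribute for parameter-recovery studies; they are not part of
#' the observable data.
#'
#' Reference labels included per subject: `macrosomia` (birth weight
#' strictly above 4000 g) and `lga` (birth weight above the 90th percentile
#' of all other subjects' true trajectory weights evaluated at this
#' subject's delivery time).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"fetal_cohort"`: a list with data frames
#'   `subjects` (one row per subject) and `visits` (long format, one row per
#'   ultrasound examination; `t` in days, biometry in mm).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  empty <- list(
    subjects = data.frame(id = integer(), age = numeric(), bmi = numeric(),
                          birth_ga = numeric(), birth_weight = numeric()),
    visits = data.frame(id = integer(), t = numeric(), bpd = numeric(),
                        mad = numeric(), fl = numeric())
  )
  if (n == 0L) {
    return(structure(empty, class = "fetal_cohort", config = config))
  }

  cov <- .draw_covariates(n)
  eff <- config$covariate_effects
  centers <- c(age = 28.32, bmi = 21.5, smoking = 1.06, hbp = 0.018,
               cardiac = 0.009, diabetes = 0.003, renal = 0.010,
               other_disease = 0.154)
  Xc <- sweep(as.matrix(cov[names(eff)]), 2, centers[names(eff)])
  amp0 <- config$birthweight_mean /
    stats::plogis((config$birth_ga_mean - config$beta2) / config$beta3)

  b <- MASS::mvrnorm(n, mu = c(0, 0, 0), Sigma = config$ranef_cov)
  b <- matrix(b, ncol = 3)
  phi1 <- amp0 + drop(Xc %*% eff) + b[, 1]
  phi2 <- config$beta2 + b[, 2]
  phi3 <- pmax(config$beta3 + b[, 3], 5) # stretch must stay positive

  last_visit <- max(config$visit_weeks) * 7
  birth_ga <- round(stats::rnorm(n, config$birth_ga_mean, config$birth_ga_sd))
  for (tries in 1:100) {
    bad <- birth_ga <= last_visit + 3
    if (!any(bad)) break
    birth_ga[bad] <- round(stats::rnorm(sum(bad), config$birth_ga_mean,
                                        config$birth_ga_sd))
  }
  if (any(birth_ga <= last_visit + 3)) {
    stop("could not draw delivery times after the last scheduled visit; ",
         "check `birth_ga_mean`/`birth_ga_sd` against `visit_weeks`")
  }

  traj <- function(i, t) phi1[i] / (1 + exp(-(t - phi2[i]) / phi3[i]))
  w_birth <- traj(seq_len(n), birth_ga)
  birth_weight <- w_birth +
    stats::rnorm(n, 0, config$sigma * abs(w_birth)^config$variance_power)

  # visit schedule with jitter, kept strictly increasing and pre-delivery
  nv <- length(config$visit_weeks)
  tv <- matrix(rep(config$visit_weeks * 7, each = n), n, nv) +
    matrix(round(stats::rnorm(n * nv, 0, config$visit_jitter_sd)), n, nv)
  tv <- t(apply(tv, 1, function(x) sort(x)))
  tv <- matrix(tv, n, nv)
  tv[tv < 80] <- 80
  tv <- pmin(tv, birth_ga - 7)

  ids <- seq_len(n)
  visits <- data.frame(
    id = rep(ids, each = nv),
    week = rep(config$visit_weeks, times = n),
    t = as.vector(t(tv))
  )
  w_vis <- phi1[visits$id] / (1 + exp(-(visits$t - phi2[visits$id]) /
                                        phi3[visits$id]))
  bio <- invert_efw(w_vis, visits$t, config$reference_formula)
  bn <- config$biometry_noise_sd
  visits$bpd <- pmax(bio$bpd + stats::rnorm(nrow(bio), 0, bn[["bpd"]]), 5)
  visits$mad <- pmax(bio$mad + stats::rnorm(nrow(bio), 0, bn[["mad"]]), 5)
  visits$fl <- pmax(bio$fl + stats::rnorm(nrow(bio), 0, bn[["fl"]]), 3)

  # reference labels: macrosomia by threshold; LGA against the 90th
  # percentile of everyone else's true trajectory weight at this delivery time
  lga <- vapply(ids, function(i) {
    refs <- phi1[-i] / (1 + exp(-(birth_ga[i] - phi2[-i]) / phi3[-i]))
    birth_weight[i] > stats::quantile(refs, 0.9, type = 7, names = FALSE)
  }, logical(1))

  subjects <- cbind(
    data.frame(id = ids), cov,
    data.frame(birth_ga = birth_ga, birth_weight = birth_weight,
               macrosomia = birth_weight > 4000, lga = lga)
  )
  structure(list(subjects = subjects, visits = visits),
            class = "fetal_cohort", config = config,
            truth = list(phi = cbind(phi1 = phi1, phi2 = phi2, phi3 = phi3),
                         amplitude_intercept = amp0,
                         covariate_centers = centers))
}

#' @export
print.fetal_cohort <- function(x, ...) {
  cat("<fetal_cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$visits), " ultrasound visits\n", sep = "")
  if (nrow(x$subjects) > 0) {
    cat(sprintf("  birth weight %.0f g (SD %.0f); macrosomia %.1f%%; LGA %.1f%%\n",
                mean(x$subjects$birth_weight), stats::sd(x$subjects$birth_weight),
                100 * mean(x$subjects$macrosomia), 100 * mean(x$subjects$lga)))
  }
  invisible(x)
}

#' Write a cohort to plain CSV files
#'
#' @param cohort A `fetal_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- file.path(dir, "subjects.csv")
  pv <- file.path(dir, "visits.csv")
  utils::write.csv(cohort$subjects, ps, row.names = FALSE)
  utils::write.csv(cohort$visits, pv, row.names = FALSE)
  invisible(c(ps, pv))
}

#' Stratified train/test split
#'
#' Splits subject ids into train and test sets stratified by a binary
#' label. The total training size is `round(train_frac * n)` (half away
#' from zero); per-stratum sizes are reconciled to that total by the
#' largest-remainder rule, so e.g. 1115 subjects at 0.7 give exactly
#' 781 train / 334 test. A stratum with fewer than 2 members is assigned
#' wholly to train with a warning.
#'
#' @param ids Vector of subject ids.
#' @param train_frac Training fraction in (0, 1).
#' @param label Binary label per id (same length), the stratification
#'   variable.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
stratified_split <- function(ids, train_frac, label, seed = 1L) {
  stopifnot(length(ids) == length(label), train_frac > 0, train_frac < 1)
  n <- length(ids)
  n_train <- floor(train_frac * n + 0.5)
  strata <- split(seq_len(n), label)
  small <- vapply(strata, length, 1L) < 2L
  if (any(small)) {
    warning("stratum with fewer than 2 members assigned wholly to train")
  }
  quota <- train_frac * vapply(strata, length, 1L)
  base <- floor(quota)
  base[small] <- vapply(strata[small], length, 1L)
  rem <- n_train - sum(base)
  if (rem > 0) {
    frac <- quota - floor(quota)
    frac[small] <- -1
    order_idx <- order(frac, decreasing = TRUE)
    take <- order_idx[seq_len(min(rem, sum(!small)))]
    base[take] <- base[take] + 1L
  } else if (rem < 0) {
    # small strata forced into train may overfill; shave the largest strata
    adjustable <- which(!small & base > 0)
    for (k in adjustable[order(base[adjustable], decreasing = TRUE)]) {
      if (rem == 0) break
      base[k] <- base[k] - 1L
      rem <- rem + 1L
    }
  }
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  train_idx <- unlist(lapply(seq_along(strata), function(k) {
    s <- strata[[k]]
    if (base[k] >= length(s)) s else sample(s, base[k])
  }), use.names = FALSE)
  list(train = ids[sort(train_idx)], test = ids[sort(setdiff(seq_len(n), train_idx))])
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
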