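test_that("a noiseless quadratic cohort is recovered exactly", {
  ids <- 1:8
  tt <- c(120, 175, 230, 260, 280)
  ts <- (tt - 210) / 35
  rows <- do.call(rbind, lapply(ids, function(i) {
    data.frame(id = i, t = tt, y = 1300 + 1000 * ts + 200 * ts^2)
  }))
  rows$id <- factor(rows$id)
  w <- rows_as_cohort(rows)
  fit <- fit_growth_model(w$cohort, w$efw, "quadratic",
                          heteroscedastic = FALSE)
  pred <- predict_weight(fit, rows$id, rows$t)
  expect_equal(pred, rows$y, tolerance = 1e-5)
  expect_equal(unname(fit$theta1), 1000, tolerance = 1e-3)
  expect_equal(unname(fit$theta2), 200, tolerance = 1e-3)
})

test_that("with no random effects the quadratic fit matches OLS (GLS oracle)", {
  set.seed(21)
  ids <- 1:12
  tt <- c(120, 175, 230, 260, 280)
  ts <- (tt - 210) / 35
  rows <- do.call(rbind, lapply(ids, function(i) {
    data.frame(id = i, t = tt, y = 1300 + 1000 * ts + 200 * ts^2 + rnorm(5, 0, 20))
  }))
  rows$id <- factor(rows$id)
  w <- rows_as_cohort(rows)
  fit <- fit_growth_model(w$cohort, w$efw, "quadratic",
                          heteroscedastic = FALSE)
  ols <- coef(lm(y ~ I((t - 210) / 35) + I(((t - 210) / 35)^2), data = rows))
  expect_equal(unname(c(fit$beta[1], fit$theta1, fit$theta2)), unname(ols),
               tolerance = 0.02)
})

test_that("the logistic fit honours the curve geometry", {
  dat <- simulate_from_logistic(120, seed = 31)
  w <- rows_as_cohort(dat)
  fit <- fit_growth_model(w$cohort, w$efw, "logistic")
  id1 <- fit$phi$id[1]
  phi <- fit$phi[1, ]
  # half-amplitude at the midpoint, full amplitude in the far limit
  expect_equal(predict_weight(fit, id1, phi$phi2), phi$phi1 / 2,
               tolerance = 1e-8)
  expect_equal(predict_weight(fit, id1, 1e6), phi$phi1, tolerance = 1e-6)
  expect_error(predict_weight(fit, "no-such-subject", 280), "unknown")
})

test_that("logistic NLS limit: no random effects, homoscedastic", {
  set.seed(41)
  n <- 60
  tt <- c(119, 175, 231, 259, 280)
  rows <- do.call(rbind, lapply(1:n, function(i) {
    mu <- 4200 / (1 + exp(-(tt - 234) / 27))
    data.frame(id = i, t = tt, y = mu + rnorm(5, 0, 40))
  }))
  rows$id <- factor(rows$id)
  w <- rows_as_cohort(rows)
  fit <- fit_growth_model(w$cohort, w$efw, "logistic",
                          heteroscedastic = FALSE)
  # pooled nonlinear least squares as the independent oracle
  nls_fit <- nls(y ~ A / (1 + exp(-(t - m) / s)), data = rows,
                 start = list(A = 4000, m = 230, s = 25))
  oracle <- coef(nls_fit)
  expect_equal(unname(fit$beta1[1]), unname(oracle["A"]), tolerance = 0.02)
  expect_equal(unname(fit$beta2), unname(oracle["m"]), tolerance = 0.02)
  expect_equal(unname(fit$beta3), unname(oracle["s"]), tolerance = 0.05)
})

test_that("masked birth weights are never read by the fit", {
  co <- tiny_cohort(n = 80, seed = 51)
  efw <- efw_records(co$visits, 5)
  test_ids <- co$subjects$id[61:80]
  fit_clean <- fit_growth_model(co, efw, "quadratic",
                                mask_birth_ids = test_ids)
  poisoned <- co
  poisoned$subjects$birth_weight[61:80] <- 1e9
  fit_poison <- fit_growth_model(poisoned, efw, "quadratic",
                                 mask_birth_ids = test_ids)
  train_ids <- co$subjects$id[1:60]
  expect_equal(predict_weight(fit_clean, train_ids, 280),
               predict_weight(fit_poison, train_ids, 280), tolerance = 1e-10)
  # masked subjects still receive predictions from their ultrasound rows
  expect_true(all(is.finite(predict_weight(fit_poison, test_ids, 280))))
  expect_true(all(predict_weight(fit_poison, test_ids, 280) < 1e5))
})

test_that("time shifts translate the logistic midpoint (equivariance)", {
  dat <- simulate_from_logistic(150, seed = 61)
  w <- rows_as_cohort(dat)
  fit0 <- fit_growth_model(w$cohort, w$efw, "logistic")
  shift <- 50
  w2 <- w
  w2$cohort$subjects$birth_ga <- w2$cohort$subjects$birth_ga + shift
  w2$efw$t <- w2$efw$t + shift
  fit1 <- fit_growth_model(w2$cohort, w2$efw, "logistic")
  expect_equal(unname(fit1$beta2 - fit0$beta2), shift, tolerance = 0.5)
  ids <- fit0$phi$id[1:10]
  expect_equal(predict_weight(fit1, ids, 280 + shift),
               predict_weight(fit0, ids, 280), tolerance = 15)
})

test_that("reported log-likelihood is non-decreasing over iterations", {
  dat <- simulate_from_logistic(100, seed = 71)
  w <- rows_as_cohort(dat)
  for (model in c("logistic", "quadratic")) {
    fit <- fit_growth_model(w$cohort, w$efw, model)
    tr <- fit$loglik_trace
    expect_gt(length(tr), 1)
    expect_true(all(diff(tr) > -1e-6 * (abs(tr[-length(tr)]) + 1)),
                label = paste(model, "likelihood ascent"))
  }
})

test_that("predictions track true birth weight on simulated cohorts", {
  co <- tiny_cohort(n = 150, seed = 81)
  efw <- efw_records(co$visits, 1)
  fit <- fit_growth_model(co, efw, "logistic")
  pbw <- predict_weight(fit, co$subjects$id, co$subjects$birth_ga)
  expect_gt(cor(pbw, co$subjects$birth_weight), 0.5)
  # fewer visits carry less information about the subject curve
  co2 <- co
  keep <- co2$visits$week <= 25
  co2$visits <- co2$visits[keep, ]
  fit2 <- fit_growth_model(co2, efw_records(co2$visits, 1), "logistic",
                           mask_birth_ids = co2$subjects$id[1:75])
  fit4 <- fit_growth_model(co, efw, "logistic",
                           mask_birth_ids = co$subjects$id[1:75])
  held <- co$subjects$id[1:75]
  ga <- co$subjects$birth_ga[1:75]
  bw <- co$subjects$birth_weight[1:75]
  expect_gt(cor(predict_weight(fit4, held, ga), bw),
            cor(predict_weight(fit2, held, ga), bw) - 0.05)
})

test_that("the two engines agree on fits of the same data", {
  dat <- simulate_from_logistic(150, seed = 91)
  w <- rows_as_cohort(dat)
  lb <- fit_growth_model(w$cohort, w$efw, "logistic", engine = "lb")
  nl <- suppressWarnings(
    fit_growth_model(w$cohort, w$efw, "logistic", engine = "nlme"))
  expect_equal(unname(lb$beta1[1]), unname(nl$beta1[1]), tolerance = 0.03)
  expect_equal(unname(lb$beta2), unname(nl$beta2), tolerance = 0.02)
  ids <- w$cohort$subjects$id
  ga <- w$cohort$subjects$birth_ga
  expect_gt(cor(predict_weight(lb, ids, ga), predict_weight(nl, ids, ga)),
            0.95)
})

test_that("fixed effects are recovered from data simulated at known truth", {
  # light version of the recovery study (the full design runs in the
  # acceptance suite): 3 replicates, generous tolerance
  truth <- c(4210, 234, 27)
  est <- sapply(1:3, function(r) {
    dat <- simulate_from_logistic(200, seed = 100 + r)
    w <- rows_as_cohort(dat)
    fit <- fit_growth_model(w$cohort, w$efw, "logistic")
    c(fit$beta1[1], fit$beta2, fit$beta3)
  })
  bias <- rowMeans(est) - truth
  expect_true(all(abs(bias / truth) < 0.05))
})
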