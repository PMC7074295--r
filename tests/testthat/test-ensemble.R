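test_that("majority voting follows the strict more-than-half rule", {
  v <- majority_vote(c(1, 1, 0))
  expect_true(v$label)
  expect_equal(v$score, 2 / 3)
  tie <- majority_vote(c(1, 0))
  expect_false(tie$label) # a tie fails the strict rule
  expect_equal(tie$score, 0.5)
  single <- majority_vote(c(TRUE))
  expect_true(single$label)
  expect_error(majority_vote(logical(0)), "at least one")
  # matrix form: score in [0,1] and label == (score > 0.5) exactly
  set.seed(17)
  M <- matrix(runif(200) > 0.4, 20, 10)
  mv <- majority_vote(M)
  expect_true(all(mv$score >= 0 & mv$score <= 1))
  expect_identical(mv$label, mv$score > 0.5)
})

test_that("selector 'none' keeps all learners; penalized selection prunes noise", {
  set.seed(18)
  n <- 250
  y <- rbinom(n, 1, 0.35)
  signal <- matrix(rep(y, 5), n, 5) # five copies of a perfect learner
  flip <- matrix(rbinom(n * 5, 1, 0.08), n, 5)
  signal <- (signal + flip) %% 2
  noise <- matrix(rbinom(n * 15, 1, 0.35), n, 15)
  feats <- cbind(signal, noise)
  colnames(feats) <- c(paste0("good", 1:5), paste0("noise", 1:15))
  expect_equal(select_learners(feats, y, "none"), colnames(feats))
  sel <- suppressWarnings(select_learners(feats, y, "scad", seed = 1,
                                          n_folds = 5))
  expect_true(any(grepl("good", sel)))
  expect_lt(sum(grepl("noise", sel)), 8)
})

test_that("an uninformative constant column receives no weight", {
  set.seed(19)
  n <- 200
  y <- rbinom(n, 1, 0.4)
  feats <- cbind(sig = (y + rbinom(n, 1, 0.1)) %% 2, allneg = rep(0, n),
                 junk = rbinom(n, 1, 0.5))
  fit <- suppressWarnings(fit_penalized_logistic(feats, y, "scad",
                                                 n_folds = 5, seed = 2))
  expect_equal(unname(fit$coefficients[["allneg"]]), 0)
})

test_that("leave-one data partitions the training set exactly once", {
  co <- tiny_cohort(n = 40, seed = 20)
  grid <- learner_grid(models = data.frame(model = "quadratic",
                                           with_covariates = FALSE),
                       formula_ids = c(1, 5))
  train <- co$subjects$id[1:30]
  meta <- suppressWarnings(
    build_leave_one_data(co, grid, train, "macrosomia", K = 3, seed = 4))
  expect_equal(nrow(meta$features), 30L)
  expect_setequal(meta$ids, train)
  expect_equal(sort(unique(meta$fold)), 1:3)
  expect_true(all(is.finite(meta$features)))
  # stratification: per-fold prevalence close to overall
  prev <- mean(meta$y)
  for (f in 1:3) {
    expect_lte(abs(mean(meta$y[meta$fold == f]) - prev),
               1 / sum(meta$fold == f) + 1e-9)
  }
})

test_that("K=2 leave-one data equals a manually performed refit", {
  co <- tiny_cohort(n = 14, seed = 21)
  grid <- learner_grid(models = data.frame(model = "quadratic",
                                           with_covariates = FALSE),
                       formula_ids = 1)
  train <- co$subjects$id
  meta <- suppressWarnings(
    build_leave_one_data(co, grid, train, "macrosomia", K = 2, seed = 7))
  s <- co$subjects
  for (f in 1:2) {
    hold <- train[meta$fold == f]
    manual <- suppressWarnings(fit_growth_model(
      co, efw_records(co$visits, 1), "quadratic", mask_birth_ids = hold))
    pred <- predict_weight(manual, hold, s$birth_ga[match(hold, s$id)])
    expect_equal(unname(meta$features[as.character(hold), 1]), unname(pred),
                 tolerance = 1e-8)
  }
})

test_that("leave-one-out on a tiny cohort matches the hand-rolled loop", {
  co <- tiny_cohort(n = 12, seed = 22)
  grid <- learner_grid(models = data.frame(model = "quadratic",
                                           with_covariates = FALSE),
                       formula_ids = 1)
  train <- co$subjects$id
  meta <- suppressWarnings(
    build_leave_one_data(co, grid, train, "macrosomia", K = 12, seed = 3))
  s <- co$subjects
  for (id in train[c(2, 7, 11)]) { # spot-check three subjects
    # folds are stratified by class, so a "fold" can hold a class-mate;
    # the oracle masks exactly the subject's fold members
    hold <- train[meta$fold == meta$fold[match(id, train)]]
    manual <- suppressWarnings(fit_growth_model(
      co, efw_records(co$visits, 1), "quadratic", mask_birth_ids = hold))
    expect_equal(unname(meta$features[as.character(id), 1]),
                 unname(predict_weight(manual, id,
                                       s$birth_ga[match(id, s$id)])),
                 tolerance = 1e-8)
  }
})

test_that("single-learner stacking reduces to simple linear regression", {
  set.seed(23)
  n <- 60
  pbw <- rnorm(n, 3500, 400)
  yw <- 200 + 0.9 * pbw + rnorm(n, 0, 100)
  meta <- list(features = matrix(pbw, dimnames = list(NULL, "only")),
               y = as.numeric(yw > 4000), y_weight = yw,
               fold = rep(1:2, 30), ids = 1:n, target = "macrosomia")
  model <- fit_stacking(meta, selector = "none")
  simple <- coef(lm(yw ~ pbw))
  expect_equal(unname(model$meta_coefficients),
               unname(simple), tolerance = 1e-8)
})

test_that("ensemble predictions respect the strict decision boundary", {
  co <- tiny_cohort(n = 20, seed = 24)
  fits <- list(a = fake_quadratic_fit(co$subjects$id, 3000, 700))
  panel <- build_learner_panel(co, fits)
  model <- structure(list(method = "stacking", selector = "none",
                          target = "macrosomia", selected_learners = "a",
                          meta_coefficients = c("(Intercept)" = 4000, a = 0),
                          meta_family = "linear", decision_threshold = 4000,
                          feature_learners = "a"),
                     class = "ensemble_model")
  pred <- predict_ensemble(model, panel)
  expect_false(any(pred$label)) # exactly 4000 is negative
  expect_true(all(pred$score == 4000))
  expect_error(predict_ensemble(
    structure(modifyList(unclass(model),
                         list(feature_learners = "missing_col")),
              class = "ensemble_model"), panel),
    "missing_col")
})

test_that("column order never changes ensemble output", {
  co <- tiny_cohort(n = 30, seed = 25)
  fits <- list(a = fake_quadratic_fit(co$subjects$id, 3000, 700),
               b = fake_quadratic_fit(co$subjects$id, 3300, 650),
               c = fake_quadratic_fit(co$subjects$id, 2800, 760))
  panel <- build_learner_panel(co, fits)
  perm <- panel
  ord <- c(3, 1, 2)
  perm$learners <- panel$learners[ord]
  perm$pbw <- panel$pbw[, ord]
  perm$macro <- panel$macro[, ord]
  perm$lga <- panel$lga[, ord]
  vote_model <- structure(list(method = "voting", selector = "none",
                               target = "macrosomia",
                               selected_learners = c("a", "b", "c"),
                               decision_threshold = 0.5),
                          class = "ensemble_model")
  expect_identical(predict_ensemble(vote_model, panel),
                   predict_ensemble(vote_model, perm))
  stack_model <- structure(list(method = "stacking", selector = "none",
                                target = "macrosomia",
                                selected_learners = c("a", "b", "c"),
                                meta_coefficients = c("(Intercept)" = 100,
                                                      a = 0.4, b = 0.3,
                                                      c = 0.3),
                                meta_family = "linear",
                                decision_threshold = 4000,
                                feature_learners = c("a", "b", "c")),
                           class = "ensemble_model")
  expect_identical(predict_ensemble(stack_model, panel),
                   predict_ensemble(stack_model, perm))
})

test_that("stacking keeps pace with a generatively correct learner", {
  co <- tiny_cohort(n = 150, seed = 26)
  s <- co$subjects
  sp <- stratified_split(s$id, 0.7, s$macrosomia, seed = 26)
  grid <- learner_grid(models = data.frame(model = c("logistic", "quadratic"),
                                           with_covariates = FALSE),
                       formula_ids = c(1, 4)) # formula 1 generates the data
  fits <- suppressWarnings(fit_learners(co, grid, mask_birth_ids = sp$test))
  panel <- suppressMessages(
    build_learner_panel(co, fits, targets = "macrosomia"))
  meta <- suppressWarnings(build_leave_one_data(co, grid, sp$train,
                                                "macrosomia", K = 3,
                                                seed = 26))
  model <- suppressWarnings(fit_stacking(meta, selector = "none"))
  pte <- panel_subset(panel, sp$test)
  yte <- s$macrosomia[match(sp$test, s$id)]
  pred <- predict_ensemble(model, pte)
  auc_ens <- roc_auc(pred$score, yte)$auc
  auc_gen <- roc_auc(pte$pbw[, "logi_f01"], yte)$auc
  expect_gte(auc_ens, auc_gen - 0.05)
})
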