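#' Learner grid: growth-model variants crossed with EFW formulas
#'
#' @param models Data frame with columns `model` ("logistic"/"quadratic")
#'   and `with_covariates` (logical); default all 4 variants.
#' @param formula_ids EFW formula ids (default all 26), giving the paper
#'   design of 4 x 26 = 104 learners.
#' @return Data frame `learner`, `model`, `with_covariates`, `formula_id`.
#' @export
learner_grid <- function(models = data.frame(
                           model = rep(c("logistic", "quadratic"), each = 2),
                           with_covariates = rep(c(FALSE, TRUE), 2)),
                         formula_ids = 1:26) {
  g <- merge(models, data.frame(formula_id = formula_ids))
  g$learner <- sprintf("%s%s_f%02d", substr(g$model, 1, 4),
                       ifelse(g$with_covariates, "c", ""), g$formula_id)
  g[order(g$learner), c("learner", "model", "with_covariates", "formula_id")]
}

#' Fit all first-level learners
#'
#' Fits one growth model per row of the learner grid. A learner whose fit
#' fails is returned as `NULL` (and excluded downstream with a message)
#' rather than aborting the run — a single ill-behaved formula must not
#' kill the pipeline.
#'
#' @param cohort A `fetal_cohort`.
#' @param grid From [learner_grid()].
#' @param mask_birth_ids Ids whose birth weights are withheld from every fit.
#' @param heteroscedastic,delta_fixed,ranef_diag Passed to [fit_growth_model()].
#' @return Named list of `growth_fit` objects (or `NULL` for failures).
#' @export
fit_learners <- function(cohort, grid, mask_birth_ids = NULL,
                         heteroscedastic = TRUE, delta_fixed = NULL,
                         ranef_diag = FALSE) {
  fits <- vector("list", nrow(grid))
  names(fits) <- grid$learner
  for (k in seq_len(nrow(grid))) {
    fits[[k]] <- tryCatch({
      efw <- efw_records(cohort$visits, grid$formula_id[k])
      fit_growth_model(cohort, efw, model = grid$model[k],
                       with_covariates = grid$with_covariates[k],
                       mask_birth_ids = mask_birth_ids,
                       heteroscedastic = heteroscedastic,
                       delta_fixed = delta_fixed, ranef_diag = ranef_diag)
    }, error = function(e) {
      warning("learner ", grid$learner[k], " failed: ", conditionMessage(e))
      NULL
    })
  }
  fits
}

#' Select first-level learners by penalized logistic regression
#'
#' Regresses the training truth on the learners' binary predictions with a
#' LASSO, SCAD or MCP penalty; the learners with nonzero coefficients at
#' the cross-validated lambda are the selected voters. An empty active set
#' falls back to all learners with a warning.
#'
#' @param features Matrix (subjects x learners) of binary training
#'   predictions (0/1 or logical).
#' @param y Binary training truth.
#' @param selector `"none"`, `"lasso"`, `"scad"` or `"mcp"`.
#' @param seed Seed for the CV folds.
#' @param n_folds CV folds for the selection fit.
#' @return Character vector of selected learner names.
#' @export
select_learners <- function(features, y,
                            selector = c("none", "lasso", "scad", "mcp"),
                            seed = 1L, n_folds = 10) {
  selector <- match.arg(selector)
  features <- as.matrix(features) * 1
  if (selector == "none") return(colnames(features))
  fit <- fit_penalized_logistic(features, y, family = selector,
                                n_folds = n_folds, seed = seed,
                                n_lambda = 50, min_ratio = 0.01)
  sel <- colnames(features)[fit$active_set]
  if (length(sel) == 0) {
    warning("penalized selection kept no learner; falling back to all")
    sel <- colnames(features)
  }
  sel
}

#' Majority vote over binary learner predictions
#'
#' The ensemble label is the class receiving strictly more than half of
#' the votes; the positive-vote fraction is returned as a graded score
#' (usable for ROC analysis). A tie therefore fails the strict rule and
#' is negative.
#'
#' @param votes Logical/0-1 vector (one subject) or matrix
#'   (subjects x learners).
#' @return List with `label` and `score`.
#' @export
majority_vote <- function(votes) {
  if (is.matrix(votes)) {
    score <- rowMeans(votes * 1)
  } else {
    if (length(votes) < 1) stop("at least one vote is required")
    score <- mean(votes * 1)
  }
  list(label = score > 0.5, score = score)
}

.cohort_subset <- function(cohort, ids) {
  keep_s <- cohort$subjects$id %in% ids
  keep_v <- cohort$visits$id %in% ids
  structure(list(subjects = cohort$subjects[keep_s, , drop = FALSE],
                 visits = cohort$visits[keep_v, , drop = FALSE]),
            class = "fetal_cohort", config = attr(cohort, "config"))
}

.truth_vector <- function(cohort, ids, target) {
  s <- cohort$subjects
  v <- if (target == "macrosomia") s$macrosomia else s$lga
  v[match(ids, s$id)]
}

#' Build the "leave-one data" for the stacking meta-learner
#'
#' K-fold cross-validation inside the training set (folds stratified by
#' the response): for each fold, every first-level learner is refitted on
#' the remaining folds (held-out birth weights masked, ultrasound rows
#' kept; subjects outside `train_ids` are excluded entirely) and its
#' predictions on the held-out fold are collected. Every training subject
#' appears in exactly one validation fold, so the meta dataset has one row
#' per training subject: learner predictions (continuous predicted birth
#' weights for macrosomia, binary LGA flags for LGA) plus the original
#' response. A learner that fails on a fold has that fold's entries
#' imputed by its training-fold feature mean, with a warning.
#'
#' @param cohort A `fetal_cohort`.
#' @param grid Learner grid (see [learner_grid()]).
#' @param train_ids Training subject ids.
#' @param target `"macrosomia"` or `"lga"`.
#' @param K Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param heteroscedastic,delta_fixed,ranef_diag Passed to the growth-model fits.
#' @return A list with `features` (matrix, train subjects x learners),
#'   `y` (binary truth), `y_weight` (observed birth weight), `fold`,
#'   `ids`.
#' @export
build_leave_one_data <- function(cohort, grid, train_ids,
                                 target = c("macrosomia", "lga"),
                                 K = 10, seed = 1L, heteroscedastic = TRUE,
                                 delta_fixed = NULL, ranef_diag = FALSE) {
  target <- match.arg(target)
  stopifnot(K >= 2)
  y <- .truth_vector(cohort, train_ids, target)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  fold <- integer(length(train_ids))
  for (cls in unique(y)) {
    k <- which(y == cls)
    fold[k] <- sample(rep_len(seq_len(K), length(k)))
  }
  train_cohort <- .cohort_subset(cohort, train_ids)
  feats <- matrix(NA_real_, length(train_ids), nrow(grid),
                  dimnames = list(train_ids, grid$learner))
  for (f in seq_len(K)) {
    hold <- train_ids[fold == f]
    fits <- fit_learners(train_cohort, grid, mask_birth_ids = hold,
                         heteroscedastic = heteroscedastic,
                         delta_fixed = delta_fixed, ranef_diag = ranef_diag)
    s <- train_cohort$subjects
    hold_ga <- s$birth_ga[match(hold, s$id)]
    for (j in seq_len(nrow(grid))) {
      fit <- fits[[j]]
      if (is.null(fit)) next # imputed below
      feats[fold == f, j] <- if (target == "macrosomia") {
        predict_weight(fit, hold, hold_ga)
      } else {
        classify_lga(function(pop, t) predict_weight(fit, pop, t),
                     ids = s$id, birth_ga = s$birth_ga, eval_ids = hold) * 1
      }
    }
  }
  if (anyNA(feats)) {
    warning("some learner-fold fits failed; imputing by training-fold means")
    for (j in seq_len(ncol(feats))) {
      miss <- is.na(feats[, j])
      if (any(miss)) feats[miss, j] <- mean(feats[!miss, j])
    }
  }
  s <- cohort$subjects
  list(features = feats, y = y * 1,
       y_weight = s$birth_weight[match(train_ids, s$id)],
       fold = fold, ids = train_ids, target = target)
}

#' Fit a stacking (super-learner) ensemble
#'
#' Trains the second-level meta-learner on the leave-one data from
#' [build_leave_one_data()]. For macrosomia the meta features are the
#' cross-validated predicted birth weights and the meta-learner is a
#' linear regression of the observed birth weight on them (unpenalized, or
#' sparsified by LASSO/SCAD/MCP); the ensemble label is meta-predicted
#' weight strictly above 4000 g. For LGA the meta features are the
#' cross-validated binary LGA flags and the meta-learner is a
#' positivity-constrained logistic regression (`selector = "none"`) or a
#' penalized logistic regression; the label is meta probability > 0.5.
#' Constant feature columns are dropped with a warning.
#'
#' @param meta Output of [build_leave_one_data()].
#' @param selector `"none"`, `"lasso"`, `"scad"` or `"mcp"`.
#' @param seed Seed for the meta-learner CV.
#' @param n_folds CV folds for penalized meta-learners.
#' @return An object of class `"ensemble_model"`.
#' @export
fit_stacking <- function(meta, selector = c("none", "lasso", "scad", "mcp"),
                         seed = 1L, n_folds = 10) {
  selector <- match.arg(selector)
  X <- meta$features
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    warning("dropping constant meta feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  target <- meta$target
  if (target == "macrosomia") {
    yw <- meta$y_weight
    if (selector == "none") {
      df <- data.frame(yw = yw, X)
      fit <- stats::lm(yw ~ ., data = df)
      cf <- stats::coef(fit)
      cf[is.na(cf)] <- 0
      intercept <- cf[1]; beta <- cf[-1]
      names(beta) <- colnames(X)
    } else {
      fit <- fit_penalized_linear(X, yw, family = selector,
                                  n_folds = n_folds, seed = seed,
                                  min_ratio = 0.01)
      intercept <- fit$intercept; beta <- fit$coefficients
    }
    meta_family <- "linear"; thr <- 4000
  } else {
    if (selector == "none") {
      fit <- fit_positive_logistic(X, meta$y)
      intercept <- fit$intercept; beta <- fit$coefficients
      meta_family <- "positive_logistic"
    } else {
      fit <- fit_penalized_logistic(X, meta$y, family = selector,
                                    n_folds = n_folds, seed = seed,
                                    min_ratio = 0.01)
      intercept <- fit$intercept; beta <- fit$coefficients
      meta_family <- "penalized_logistic"
    }
    thr <- 0.5
  }
  sel <- names(beta)[beta != 0]
  if (length(sel) == 0) sel <- names(beta)
  structure(list(method = "stacking", selector = selector, target = target,
                 selected_learners = sel,
                 meta_coefficients = c("(Intercept)" = unname(intercept), beta),
                 meta_family = meta_family, decision_threshold = thr,
                 feature_learners = colnames(X)),
            class = "ensemble_model")
}

#' Fit a majority-voting ensemble
#'
#' Optionally selects voters by penalized logistic regression of the
#' training truth on the learners' binary training predictions, then votes.
#'
#' @param panel Training `learner_panel`.
#' @param y Binary training truth aligned with `panel$ids`.
#' @param target `"macrosomia"` or `"lga"`.
#' @param selector Learner-selection penalty (or `"none"`).
#' @param seed,n_folds Passed to [select_learners()].
#' @return An `ensemble_model`.
#' @export
fit_voting <- function(panel, y, target = c("macrosomia", "lga"),
                       selector = c("none", "lasso", "scad", "mcp"),
                       seed = 1L, n_folds = 10) {
  target <- match.arg(target)
  selector <- match.arg(selector)
  M <- if (target == "macrosomia") panel$macro else panel$lga
  keep <- apply(M, 2, function(v) stats::sd(v) > 0)
  feats <- M[, keep, drop = FALSE]
  sel <- if (selector == "none" || ncol(feats) == 0) {
    colnames(M)
  } else {
    select_learners(feats, y, selector, seed = seed, n_folds = n_folds)
  }
  structure(list(method = "voting", selector = selector, target = target,
                 selected_learners = sel, meta_coefficients = NULL,
                 meta_family = NULL, decision_threshold = 0.5),
            class = "ensemble_model")
}

#' Predict from a fitted ensemble
#'
#' Applies the voting rule or the meta-learner to a `learner_panel`
#' (typically the held-out test subjects). Returns the binary labels and a
#' real-valued score suitable for ROC analysis: the positive-vote fraction
#' for voting, the meta-predicted weight (macrosomia) or the meta
#' probability (LGA) for stacking.
#'
#' @param model An `ensemble_model`.
#' @param panel A `learner_panel` containing all learners the model needs.
#' @return List with `label` and `score` along `panel$ids`.
#' @export
predict_ensemble <- function(model, panel) {
  need <- if (model$method == "voting") model$selected_learners
          else model$feature_learners
  missing <- setdiff(need, panel$learners)
  if (length(missing)) {
    stop("panel lacks learner column(s): ", paste(missing, collapse = ", "))
  }
  if (model$method == "voting") {
    M <- if (model$target == "macrosomia") panel$macro else panel$lga
    return(majority_vote(M[, model$selected_learners, drop = FALSE]))
  }
  X <- if (model$target == "macrosomia") panel$pbw else panel$lga * 1
  X <- X[, model$feature_learners, drop = FALSE]
  cf <- model$meta_coefficients
  eta <- cf[1] + drop(X %*% cf[-1])
  if (model$meta_family == "linear") {
    list(label = eta > model$decision_threshold, score = eta)
  } else {
    p <- stats::plogis(eta)
    list(label = p > model$decision_threshold, score = p)
  }
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", x$method, " / ", x$selector, " for ", x$target,
      "; ", length(x$selected_learners), " learner(s)\n", sep = "")
  invisible(x)
}
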