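#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. The default mirrors the full
#' study design (1115 subjects, all 26 formulas, all 4 model variants,
#' 70/30 stratified split, 10-fold stacking CV); smaller configurations
#' are used for routine testing.
#'
#' @param n_subjects Cohort size.
#' @param formula_ids EFW formula ids to use.
#' @param models Growth-model variant grid (see [learner_grid()]).
#' @param train_frac Training fraction for the stratified split.
#' @param K Folds for the stacking leave-one data.
#' @param selectors Selection penalties to run for both ensemble methods.
#' @param targets Prediction targets.
#' @param stacking Also fit stacking ensembles (needs K-fold learner
#'   refits; the expensive part).
#' @param heteroscedastic Power-variance errors in the growth models.
#' @param seed Master seed.
#' @param sim Optional pre-built [sim_config()]; overrides `n_subjects`
#'   and `seed` for the simulation stage.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_subjects = 1115, formula_ids = 1:26,
                            models = NULL, train_frac = 0.7, K = 10,
                            selectors = c("none", "lasso", "scad", "mcp"),
                            targets = c("macrosomia", "lga"),
                            stacking = TRUE, heteroscedastic = TRUE,
                            seed = 1L, sim = NULL) {
  if (is.null(models)) {
    models <- data.frame(model = rep(c("logistic", "quadratic"), each = 2),
                         with_covariates = rep(c(FALSE, TRUE), 2))
  }
  stopifnot(train_frac > 0, train_frac < 1,
            all(formula_ids %in% 1:26))
  structure(list(n_subjects = n_subjects, formula_ids = formula_ids,
                 models = models, train_frac = train_frac, K = K,
                 selectors = selectors, targets = targets,
                 stacking = stacking, heteroscedastic = heteroscedastic,
                 seed = as.integer(seed), sim = sim),
            class = "pipeline_config")
}

#' Run the full four-step pipeline
#'
#' simulate -> EFW -> growth-model learners -> classification panel ->
#' ensembles -> evaluation. Learners are fitted once on the training rows
#' plus the test subjects' ultrasound rows with the test birth weights
#' masked; test birth weights and true labels are touched only inside
#' [evaluate_all()]. Returns per-learner and per-ensemble metric tables
#' for each target, with the configuration and seed echoed.
#'
#' @param config A [pipeline_config()].
#' @return List of class `"pipeline_result"`: `learner_metrics`,
#'   `ensemble_metrics`, `split`, `panel`, `ensembles`, `config`.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  simc <- if (!is.null(config$sim)) config$sim else
    sim_config(n_subjects = config$n_subjects, seed = config$seed)
  cohort <- simulate_cohort(simc)
  s <- cohort$subjects
  stratum <- interaction(s$macrosomia, s$lga, drop = TRUE)
  split <- stratified_split(s$id, config$train_frac, stratum,
                            seed = config$seed)
  grid <- learner_grid(config$models, config$formula_ids)
  fits <- fit_learners(cohort, grid, mask_birth_ids = split$test,
                       heteroscedastic = config$heteroscedastic)
  panel <- build_learner_panel(cohort, fits)

  ensembles <- list()
  for (target in config$targets) {
    y_train <- .truth_vector(cohort, split$train, target)
    panel_train <- panel_subset(panel, split$train)
    for (sel in config$selectors) {
      ensembles[[paste("voting", sel, target, sep = ".")]] <-
        fit_voting(panel_train, y_train, target = target, selector = sel,
                   seed = config$seed)
    }
    if (config$stacking) {
      meta <- build_leave_one_data(cohort, grid, split$train,
                                   target = target, K = config$K,
                                   seed = config$seed,
                                   heteroscedastic = config$heteroscedastic)
      for (sel in config$selectors) {
        ensembles[[paste("stacking", sel, target, sep = ".")]] <-
          fit_stacking(meta, selector = sel, seed = config$seed)
      }
    }
  }

  truth_test <- s[match(split$test, s$id),
                  c("id", "macrosomia", "lga", "birth_weight")]
  eval_tables <- evaluate_all(panel_subset(panel, split$test), truth_test,
                              ensembles)
  structure(c(eval_tables,
              list(split = split, panel = panel, ensembles = ensembles,
                   config = config, seed = config$seed)),
            class = "pipeline_result")
}

#' Evaluate learners and ensembles on the test subjects
#'
#' The only stage that reads the held-out truth. Produces one metric row
#' per individual learner and per ensemble, for each target. Individual
#' learners are scored by their predicted birth weight (macrosomia) or by
#' their binary LGA flag; single-class truth flags the AUC as missing but
#' the rates are still reported.
#'
#' @param panel_test `learner_panel` restricted to the test subjects.
#' @param truth Data frame `id`, `macrosomia`, `lga` for the test subjects.
#' @param ensembles Named list of `ensemble_model`s.
#' @return List `learner_metrics`, `ensemble_metrics` (data frames).
#' @export
evaluate_all <- function(panel_test, truth, ensembles = list()) {
  stopifnot(identical(as.character(panel_test$ids), as.character(truth$id)))
  both_targets <- c("macrosomia", "lga")
  lm_rows <- list()
  for (target in both_targets) {
    tr <- truth[[target]]
    single_class <- length(unique(as.logical(tr))) < 2
    for (ln in panel_test$learners) {
      labels <- if (target == "macrosomia") panel_test$macro[, ln]
                else panel_test$lga[, ln]
      scores <- if (target == "macrosomia") panel_test$pbw[, ln]
                else panel_test$lga[, ln] * 1
      row <- metrics_report(labels, if (single_class) NULL else scores, tr)
      lm_rows[[paste(target, ln)]] <-
        cbind(data.frame(target = target, learner = ln), row)
    }
  }
  en_rows <- list()
  for (nm in names(ensembles)) {
    model <- ensembles[[nm]]
    tr <- truth[[model$target]]
    pred <- predict_ensemble(model, panel_test)
    single_class <- length(unique(as.logical(tr))) < 2
    row <- metrics_report(pred$label, if (single_class) NULL else pred$score,
                          tr)
    en_rows[[nm]] <- cbind(
      data.frame(method = model$method, selector = model$selector,
                 target = model$target), row)
  }
  list(
    learner_metrics = do.call(rbind, c(lm_rows, list(make.row.names = FALSE))),
    ensemble_metrics = if (length(en_rows))
      do.call(rbind, c(en_rows, list(make.row.names = FALSE))) else NULL
  )
}
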