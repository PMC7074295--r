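#' Macrosomia classification from predicted birth weight
#'
#' Macrosomia is a birth weight of *more than* 4000 g regardless of
#' gestational age; the inequality is strict, so exactly 4000 g is
#' negative.
#'
#' @param pbw Predicted (or observed) birth weight(s) in grams, finite.
#' @param threshold Weight threshold in grams (default 4000).
#' @return Logical vector.
#' @export
classify_macrosomia <- function(pbw, threshold = 4000) {
  if (any(!is.finite(pbw))) stop("`pbw` must be finite")
  pbw > threshold
}

#' LGA classification by the counterfactual 90th-percentile rule
#'
#' A fetus is large-for-gestational-age if its predicted weight at its own
#' delivery time exceeds (strictly) the 90th percentile of the predicted
#' weights of *all other* fetuses evaluated at that same delivery time —
#' i.e. everyone is counterfactually "born" at the index subject's
#' delivery time, and the index subject must sit above the 90th centile of
#' that reference distribution. The percentile is the linear-interpolation
#' sample quantile (R type 7).
#'
#' @param pred_fun Function `(ids, t) -> weights` returning every subject's
#'   predicted weight at time `t` (e.g. a closure over [predict_weight()]).
#' @param ids All subject ids in the reference population.
#' @param birth_ga Delivery time in days for each id.
#' @param eval_ids Ids to classify (default: all of `ids`).
#' @return Logical vector along `eval_ids`.
#' @export
classify_lga <- function(pred_fun, ids, birth_ga, eval_ids = ids) {
  stopifnot(length(ids) == length(birth_ga))
  if (length(ids) < 11) {
    warning("fewer than 10 reference subjects for the LGA percentile")
  }
  idx <- match(eval_ids, ids)
  if (any(is.na(idx))) stop("eval_ids must be a subset of ids")
  vapply(idx, function(i) {
    v <- pred_fun(ids, birth_ga[i])
    v[i] > stats::quantile(v[-i], 0.9, type = 7, names = FALSE)
  }, logical(1))
}

#' Build the learner panel: PBWs and classifications for every learner
#'
#' A "learner" is one growth-model variant (logistic/quadratic, with or
#' without covariates) combined with one EFW formula; the full design is
#' 4 x 26 = 104 learners. For each fitted learner the panel holds every
#' subject's predicted birth weight at their own delivery time, the
#' macrosomia flag, and the LGA flag under the counterfactual percentile
#' rule computed from that learner's own curves. Learners whose fit failed
#' are recorded in `failed` and excluded from the matrices.
#'
#' @param cohort A `fetal_cohort`.
#' @param fits Named list of `growth_fit` objects (names are learner ids);
#'   elements may be `NULL` for failed fits.
#' @param lga_reference_ids Ids forming the LGA reference population
#'   (default: all subjects in the cohort).
#' @param targets Which classifications to compute; dropping `"lga"` skips
#'   the O(n^2) counterfactual-percentile pass.
#' @return An object of class `"learner_panel"`: subject `ids`, `learners`,
#'   numeric matrix `pbw`, logical matrices `macro` and `lga`
#'   (subjects x learners), and `failed`.
#' @export
build_learner_panel <- function(cohort, fits,
                                lga_reference_ids = cohort$subjects$id,
                                targets = c("macrosomia", "lga")) {
  subjects <- cohort$subjects
  ids <- subjects$id
  ok <- !vapply(fits, is.null, logical(1))
  failed <- names(fits)[!ok]
  if (length(failed)) {
    message("learner panel: excluding failed learners: ",
            paste(failed, collapse = ", "))
  }
  fits <- fits[ok]
  ref_idx <- match(lga_reference_ids, ids)
  pbw <- matrix(NA_real_, length(ids), length(fits),
                dimnames = list(ids, names(fits)))
  macro <- lga <- matrix(NA, length(ids), length(fits),
                         dimnames = list(ids, names(fits)))
  for (j in seq_along(fits)) {
    f <- fits[[j]]
    pbw[, j] <- predict_weight(f, ids, subjects$birth_ga)
    macro[, j] <- classify_macrosomia(pbw[, j])
    if ("lga" %in% targets) {
      lga[, j] <- classify_lga(
        function(pop, t) predict_weight(f, pop, t),
        ids = ids[ref_idx], birth_ga = subjects$birth_ga[ref_idx],
        eval_ids = ids
      )
    }
  }
  structure(list(ids = ids, learners = names(fits), pbw = pbw,
                 macro = macro, lga = lga, failed = failed),
            class = "learner_panel")
}

#' @export
print.learner_panel <- function(x, ...) {
  cat("<learner_panel> ", length(x$ids), " subjects x ", length(x$learners),
      " learners", if (length(x$failed)) paste0(" (", length(x$failed),
                                                " failed)"), "\n", sep = "")
  invisible(x)
}

#' Subset a learner panel by subjects
#' @param panel A `learner_panel`.
#' @param ids Subject ids to keep.
#' @return A `learner_panel` restricted to `ids`.
#' @export
panel_subset <- function(panel, ids) {
  k <- match(ids, panel$ids)
  if (any(is.na(k))) stop("unknown subject id(s) in panel subset")
  structure(list(ids = panel$ids[k], learners = panel$learners,
                 pbw = panel$pbw[k, , drop = FALSE],
                 macro = panel$macro[k, , drop = FALSE],
                 lga = panel$lga[k, , drop = FALSE],
                 failed = panel$failed),
            class = "learner_panel")
}
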