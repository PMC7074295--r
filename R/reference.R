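#' Reference fetal biometry by gestational age
#'
#' Smooth monotone reference curves for BPD, MAD and FL used by the
#' synthetic cohort generator and by formula-bank validation grids. The
#' curves are monotone Hyman splines through round-number anchors typical
#' of published biometry charts (weeks 12 to 42); they describe a median
#' fetus and carry no population claim beyond plausibility.
#'
#' @param t Gestational age in days (vectorised).
#' @return A data frame with columns `bpd`, `mad`, `fl` in mm.
#' @export
reference_biometry <- function(t) {
  wk <- t / 7
  anchors_wk <- c(12, 17, 25, 33, 40, 42)
  bpd <- stats::splinefun(anchors_wk, c(21, 38, 62, 83, 95, 97),
                          method = "hyman")
  mad <- stats::splinefun(anchors_wk, c(18, 35, 65, 92, 106, 110),
                          method = "hyman")
  fl <- stats::splinefun(anchors_wk, c(8, 24, 46, 64, 73, 75.5),
                         method = "hyman")
  data.frame(bpd = bpd(wk), mad = mad(wk), fl = fl(wk))
}

#' Invert an EFW formula against a target weight
#'
#' Finds the biometry triplet whose shape follows the gestational-age
#' reference proportions of [reference_biometry()] and whose estimated
#' fetal weight under `formula_id` equals `weight`. The triplet is the
#' reference triplet at `t` scaled by a common factor found by root
#' bisection; scaling all three measures together keeps the EFW-biometry
#' relation self-consistent so that re-applying the formula recovers the
#' target weight exactly.
#'
#' @param weight Target weight(s) in grams (positive).
#' @param t Gestational age(s) in days, same length as `weight` (or length 1).
#' @param formula_id Formula used for the inversion (default 1).
#' @return Data frame `bpd`, `mad`, `fl` in mm.
#' @export
invert_efw <- function(weight, t, formula_id = 1L) {
  n <- max(length(weight), length(t))
  weight <- rep_len(weight, n)
  t <- rep_len(t, n)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("`weight` must be finite and positive")
  }
  ref <- reference_biometry(t)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("bpd", "mad", "fl")))
  for (i in seq_len(n)) {
    base <- as.numeric(ref[i, ])
    efw_at <- function(s) {
      estimate_fetal_weight(formula_id, list(bpd = s * base[1],
                                             mad = s * base[2],
                                             fl = s * base[3]))
    }
    # Bracket by coarse grid before root-polishing: log-form formulas have
    # a positive floor as biometry shrinks and some are non-monotone far
    # outside the physiologic range, so targets beyond the attainable span
    # (possible only in extreme trajectory tails) are clamped to it.
    grid <- seq(0.05, 3, length.out = 60)
    vals <- estimate_fetal_weight(formula_id,
                                  list(bpd = grid * base[1],
                                       mad = grid * base[2],
                                       fl = grid * base[3]))
    target <- min(max(weight[i], min(vals) * 1.001), max(vals) * 0.999)
    k <- which(vals[-1] >= target & vals[-length(vals)] <= target)[1]
    s <- stats::uniroot(function(s) efw_at(s) - target,
                        c(grid[k], grid[k + 1]), tol = 1e-8)$root
    out[i, ] <- s * base
  }
  as.data.frame(out)
}
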