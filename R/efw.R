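#' Abdominal circumference from middle abdominal diameter
#'
#' Converts a middle abdominal diameter (MAD) to an abdominal circumference
#' (AC) using the conventional circular approximation `AC = 3.1416 * MAD`.
#' The constant 3.1416 (not `pi`) is used deliberately: it is the rounded
#' constant in routine sonographic practice for this conversion, and the
#' formula bank's AC-based models were calibrated against circumferences
#' computed this way.
#'
#' @param mad Middle abdominal diameter in mm (vectorised, non-negative).
#' @return Abdominal circumference in mm.
#' @export
#' @examples
#' abdominal_circumference(100) # 314.16
abdominal_circumference <- function(mad) {
  if (any(!is.finite(mad)) || any(mad < 0)) {
    stop("`mad` must be finite and non-negative")
  }
  3.1416 * mad
}

#' Head circumference derived from biparietal diameter
#'
#' The ultrasound records carry only BPD, MAD and FL, but several formulas
#' in the bank require a head circumference. HC is derived from BPD by a
#' configurable linear rule `HC = intercept + slope * BPD`. The default
#' slope 3.58 is the perimeter of an ellipse with cephalic index 0.78
#' (occipitofrontal diameter = BPD / 0.78): `pi * BPD * (1 + 1/0.78) / 2`.
#' Override via `options(fetalens.hc.coef = c(intercept, slope))` or the
#' `coef` argument.
#'
#' @param bpd Biparietal diameter in mm (vectorised, positive).
#' @param coef Numeric length-2 vector `c(intercept, slope)`, slope > 0 so
#'   that HC is strictly increasing in BPD.
#' @return Head circumference in mm.
#' @export
head_circumference <- function(bpd,
                               coef = getOption("fetalens.hc.coef",
                                                c(0, 3.58))) {
  if (is.null(coef)) {
    stop("no HC formula configured: set option 'fetalens.hc.coef' to ",
         "c(intercept, slope)")
  }
  coef <- as.numeric(coef)
  if (length(coef) != 2L || any(!is.finite(coef)) || coef[2L] <= 0) {
    stop("'fetalens.hc.coef' must be c(intercept, slope) with slope > 0")
  }
  if (any(!is.finite(bpd)) || any(bpd <= 0)) {
    stop("`bpd` must be finite and positive")
  }
  coef[1L] + coef[2L] * bpd
}

.efw_bank_cache <- new.env(parent = emptyenv())

#' The bank of 26 sonographic estimated-fetal-weight formulas
#'
#' Loads the formula bank shipped with the package: 26 published empirical
#' formulas mapping fetal biometry (BPD, MAD, FL, and the derived AC and HC)
#' to an estimated fetal weight in grams. Coefficients live in
#' `inst/extdata/efw_formulas.json`, not in code, so the bank is versioned
#' and auditable; ids are stable and are the ids used everywhere downstream
#' (learner names, reports).
#'
#' @return A data frame with one row per formula and columns `id`, `name`,
#'   `inputs` (list column of required biometry), `family` (functional-form
#'   tag) and `expr` (the evaluated expression, biometry in cm, result in g).
#' @export
#' @examples
#' nrow(list_formulas()) # 26
list_formulas <- function() {
  if (!is.null(.efw_bank_cache$bank)) {
    return(.efw_bank_cache$bank)
  }
  path <- system.file("extdata", "efw_formulas.json", package = "fetalens")
  if (path == "") { # pre-installation fallback (e.g. pkgload)
    path <- file.path("inst", "extdata", "efw_formulas.json")
  }
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  bank <- raw$formulas
  bank$inputs <- lapply(seq_len(nrow(bank)), function(i) unlist(bank$inputs[i]))
  stopifnot(identical(sort(bank$id), 1:26))
  .efw_bank_cache$bank <- bank
  bank
}

.formula_spec <- function(formula_id) {
  bank <- list_formulas()
  row <- bank[bank$id == formula_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown formula id: ", formula_id)
  row
}

#' Estimated fetal weight from biometry
#'
#' Evaluates one formula of the bank on biometry measured in mm. AC and HC
#' are derived on the fly (AC = 3.1416 x MAD; HC from BPD via
#' [head_circumference()]), identically for every formula that demands
#' them. Expressions are evaluated in cm, the unit in which the formulas
#' were published; results are grams.
#'
#' @param formula_id Integer id in 1..26 (see [list_formulas()]).
#' @param biometry A list or data frame with numeric elements `bpd`, `mad`,
#'   `fl` in mm (each vectorised to a common length; a required element may
#'   be omitted only if the formula does not use it directly or indirectly).
#' @return Estimated fetal weight(s) in grams.
#' @export
estimate_fetal_weight <- function(formula_id, biometry) {
  spec <- .formula_spec(formula_id)
  need <- spec$inputs[[1L]]
  vars <- list()
  get_mm <- function(name) {
    v <- biometry[[name]]
    if (is.null(v) || any(is.na(v))) {
      stop("formula ", spec$id, " (", spec$name, ") requires input '",
           toupper(name), "' which is missing or NA")
    }
    v
  }
  # derive everything the expression might mention, in cm
  if (any(c("BPD", "HC") %in% need)) vars$bpd <- get_mm("bpd") / 10
  if (any(c("MAD", "AC") %in% need)) vars$mad <- get_mm("mad") / 10
  if ("FL" %in% need) vars$fl <- get_mm("fl") / 10
  if ("AC" %in% need) vars$ac <- abdominal_circumference(vars$mad * 10) / 10
  if ("HC" %in% need) vars$hc <- head_circumference(vars$bpd * 10) / 10
  key <- as.character(spec$id)
  if (is.null(.efw_bank_cache$parsed)) .efw_bank_cache$parsed <- list()
  expr <- .efw_bank_cache$parsed[[key]]
  if (is.null(expr)) {
    expr <- parse(text = spec$expr)[[1]]
    .efw_bank_cache$parsed[[key]] <- expr
  }
  efw <- eval(expr, envir = vars, enclos = baseenv())
  if (any(!is.finite(efw))) {
    stop("formula ", spec$id, " (", spec$name, ") produced a non-finite ",
         "estimated weight")
  }
  efw
}

#' Estimated fetal weights for a table of ultrasound visits
#'
#' Convenience wrapper applying [estimate_fetal_weight()] to a long-format
#' visit table.
#'
#' @param visits Data frame with columns `id`, `t` (gestational age, days),
#'   `bpd`, `mad`, `fl` (mm).
#' @param formula_id Formula id in 1..26.
#' @return Data frame `id`, `t`, `formula_id`, `efw` (g).
#' @export
efw_records <- function(visits, formula_id) {
  stopifnot(all(c("id", "t", "bpd", "mad", "fl") %in% names(visits)))
  data.frame(
    id = visits$id,
    t = visits$t,
    formula_id = formula_id,
    efw = estimate_fetal_weight(formula_id, visits),
    stringsAsFactors = FALSE
  )
}
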