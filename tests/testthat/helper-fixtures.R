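# Small in-code fixtures shared across tests.

# compact cohort for pipeline-level tests
tiny_cohort <- function(n = 60, seed = 42, ...) {
  simulate_cohort(sim_config(n_subjects = n, seed = seed, ...))
}

# a hand-built quadratic growth_fit whose curves we control exactly;
# coefficients are on the internal ts = (t - 210)/35 scale
fake_quadratic_fit <- function(ids, a0, a1 = 0, a2 = 0) {
  structure(list(
    model = "quadratic",
    coefs = data.frame(id = as.character(ids),
                       a0 = rep_len(a0, length(ids)),
                       a1 = rep_len(a1, length(ids)),
                       a2 = rep_len(a2, length(ids))),
    t_center = 210, t_scale = 35,
    converged = TRUE, with_covariates = FALSE,
    subject_ids = as.character(ids)
  ), class = "growth_fit")
}

simulate_from_logistic <- function(n, seed, ...) {
  simulate_growth_data("logistic", n, seed, ...)
}

simulate_from_quadratic <- function(n, seed, ...) {
  simulate_growth_data("quadratic", n, seed, ...)
}

rows_as_cohort <- function(dat) fetalens:::.rows_as_cohort(dat)

published_tables <- function() {
  path <- system.file("extdata", "published_ensemble_performance.csv",
                      package = "fetalens")
  read.csv(path, stringsAsFactors = FALSE)
}
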