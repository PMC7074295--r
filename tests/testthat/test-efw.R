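test_that("abdominal circumference uses the conventional 3.1416 constant", {
  expect_equal(abdominal_circumference(100), 314.16)
  expect_equal(abdominal_circumference(0), 0)
  expect_equal(abdominal_circumference(87.3), 274.26168)
  expect_false(identical(abdominal_circumference(1), pi)) # not base pi
  expect_error(abdominal_circumference(-1), "non-negative")
})

test_that("head circumference is configurable and strictly increasing", {
  bpd <- seq(20, 110, by = 5)
  hc <- head_circumference(bpd)
  expect_true(all(diff(hc) > 0))
  expect_equal(head_circumference(30, coef = c(0, 3.1)), 93)
  withr::with_options(list(fetalens.hc.coef = c(0, 3.1)), {
    expect_equal(head_circumference(30), 93)
  })
  expect_error(head_circumference(30, coef = NULL), "fetalens.hc.coef")
  expect_error(head_circumference(30, coef = c(0, -1)), "slope > 0")
  # default linear rule frozen: 3.58 mm of HC per mm of BPD
  expect_equal(head_circumference(90), 322.2, tolerance = 1e-10)
})

test_that("the bank holds exactly 26 formulas with valid input sets", {
  bank <- list_formulas()
  expect_equal(nrow(bank), 26L)
  expect_equal(sort(bank$id), 1:26)
  allowed <- c("AC", "BPD", "FL", "HC", "MAD")
  for (i in seq_len(26)) {
    expect_true(all(bank$inputs[[i]] %in% allowed))
    expect_gt(length(bank$inputs[[i]]), 0)
  }
})

test_that("EFW evaluation matches independent hand arithmetic", {
  # Shepard (bank id 4), bpd 90 mm, mad 100 mm:
  # log10(kg) = -1.7492 + 0.166*9 + 0.046*(3.1416*10) - 0.002646*(3.1416*10)*9
  expected4 <- 1000 * 10^(-1.7492 + 0.166 * 9 + 0.046 * 31.416 -
                          0.002646 * 31.416 * 9)
  expect_equal(estimate_fetal_weight(4, list(bpd = 90, mad = 100)),
               expected4, tolerance = 1e-12)
  # Campbell & Wilkin (id 2), mad 100 mm: ln(kg) = -4.564 + .282*AC - .00331*AC^2
  expected2 <- 1000 * exp(-4.564 + 0.282 * 31.416 - 0.00331 * 31.416^2)
  expect_equal(estimate_fetal_weight(2, list(mad = 100)), expected2,
               tolerance = 1e-12)
  # Thurnau (id 15) is linear: 9.337*bpd_cm*ac_cm - 299
  expect_equal(estimate_fetal_weight(15, list(bpd = 90, mad = 100)),
               9.337 * 9 * 3.1416 * 10 - 299, tolerance = 1e-12)
})

test_that("every formula is finite and positive across gestation", {
  t <- seq(17, 40, by = 0.5) * 7
  for (scale in c(0.9, 1, 1.1)) {
    ref <- reference_biometry(t)
    ref[] <- lapply(ref, function(v) v * scale)
    for (id in 1:26) {
      w <- estimate_fetal_weight(id, ref)
      expect_true(all(is.finite(w)) && all(w > 0),
                  label = sprintf("formula %d at scale %.1f", id, scale))
    }
  }
})

test_that("AC-based formulas increase with abdominal size", {
  base <- list(bpd = 90, mad = 100, fl = 70)
  for (id in c(2, 4, 6, 7, 14, 21, 26)) {
    lo <- estimate_fetal_weight(id, base)
    hi <- estimate_fetal_weight(id, modifyList(base, list(mad = 105)))
    expect_gt(hi, lo, label = sprintf("formula %d monotone in MAD/AC", id))
  }
})

test_that("a missing required input names the offending variable", {
  expect_error(estimate_fetal_weight(6, list(mad = 100)), "FL")
  expect_error(estimate_fetal_weight(4, list(mad = 100)), "BPD")
  expect_error(estimate_fetal_weight(99, list(mad = 100)), "unknown formula")
})

test_that("inverting the reference formula round-trips the target weight", {
  t <- c(120, 180, 240, 280)
  w <- c(150, 800, 2200, 3600)
  bio <- invert_efw(w, t, formula_id = 1L)
  back <- estimate_fetal_weight(1, bio)
  expect_equal(back, w, tolerance = 1e-6)
  # and the noiseless simulated biometry reproduces the true curves
  cfg <- sim_config(n_subjects = 40, seed = 3,
                    biometry_noise_sd = c(bpd = 0, mad = 0, fl = 0))
  co <- simulate_cohort(cfg)
  truth <- attr(co, "truth")$phi
  i <- co$visits$id
  w_true <- truth[i, "phi1"] /
    (1 + exp(-(co$visits$t - truth[i, "phi2"]) / truth[i, "phi3"]))
  efw <- estimate_fetal_weight(1, co$visits)
  keep <- w_true > 50 # below the formula floor the generator clamps
  expect_equal(efw[keep], w_true[keep], tolerance = 1e-4)
})
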