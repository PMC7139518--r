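test_that("patient beta1 inference inverts the blood profile exactly", {
  r <- cd8_controls()
  cp <- compartment_profile(steady_state(r))
  expect_equal(infer_patient_beta1(cp$pb_naive_frac, r), r$beta1,
               tolerance = 1e-10)
  expect_equal(infer_patient_beta1(1, r), 0)
  expect_equal(infer_patient_beta1(0, r), 1 - r$alpha1)
  expect_error(infer_patient_beta1(1.2, r), "\\[0, 1\\]")
})

test_that("blood-only prediction round-trips the cohort model", {
  R <- random_valid_rates(25, seed = 31)
  for (i in seq_len(nrow(R))) {
    r <- rates_from_row(R[i, ])
    cp <- tryCatch(compartment_profile(steady_state(r)),
                   error = function(e) NULL)
    if (is.null(cp)) next # degenerate compartment, nothing to round trip
    pred <- predict_csf(c(cp$pb_naive_frac, cp$pb_diff_frac), r)
    expect_equal(pred$csf_naive_frac, cp$csf_naive_frac, tolerance = 1e-10)
    expect_equal(pred$csf_diff_frac, cp$csf_diff_frac, tolerance = 1e-10)
  }
})

test_that("an all-naive blood profile gives the no-differentiation closed form", {
  r <- cd8_controls()
  pred <- predict_csf(c(1, 0), r)
  expect_equal(pred$patient_beta1, 0)
  expect_equal(pred$csf_diff_frac, r$beta2 / (1 + r$beta2),
               tolerance = 1e-12)
  expect_equal(pred$csf_diff_frac, 0.16510, tolerance = 1e-4)
})

test_that("ill-formed blood profiles are rejected", {
  expect_error(predict_csf(c(0.5, 0.6), cd8_controls()), "sum to 1")
})

test_that("more naive blood means no more differentiated CSF", {
  r <- cd8_controls()
  preds <- sapply(seq(0.02, 0.98, by = 0.06), function(p)
    predict_csf(p, r)$csf_diff_frac)
  expect_true(all(diff(preds) <= 1e-12))
})

test_that("bootstrap prediction is reproducible and collapses without resampling", {
  truth <- cd8_controls()
  cohort <- generate_cohort(truth, generator_config(12, seed = 5))
  opts <- calibration_options(multistart = 1)

  b0 <- bootstrap_prediction(cohort, c(0.85, 0.92), B = 1, seed = 1,
                             options = opts, resample = FALSE)
  expect_equal(b0$csf_naive_low, b0$csf_naive_frac, tolerance = 1e-12)
  expect_equal(b0$csf_naive_high, b0$csf_naive_frac, tolerance = 1e-12)

  b1 <- bootstrap_prediction(cohort, 0.9, B = 20, seed = 7, options = opts)
  b2 <- bootstrap_prediction(cohort, 0.9, B = 20, seed = 7, options = opts)
  expect_identical(b1, b2)
  expect_true(all(b1$csf_naive_low <= b1$csf_naive_high))
})

test_that("bootstrap intervals tighten as the training cohort grows", {
  truth <- cd8_controls()
  opts <- calibration_options(multistart = 1)
  width_at <- function(K) {
    cohort <- generate_cohort(truth, generator_config(K, seed = 9))
    b <- bootstrap_prediction(cohort, c(0.8, 0.9, 0.95), B = 100, seed = 13,
                              options = opts)
    stats::median(b$csf_naive_high - b$csf_naive_low)
  }
  expect_lt(width_at(100), width_at(14))
})

test_that("bootstrap intervals usually cover the generating CSF profile", {
  truth <- reference_rates("CD8", "SuS")
  target <- compartment_profile(steady_state(truth))$csf_naive_frac
  cohort <- generate_cohort(truth, generator_config(14, seed = 17))
  new_pb <- generate_cohort(truth, generator_config(19, seed = 18))
  b <- bootstrap_prediction(cohort, new_pb$pb_naive_pct / 100,
                            B = 200, seed = 19,
                            options = calibration_options(multistart = 1))
  covered <- b$csf_naive_low <= target & target <= b$csf_naive_high
  expect_gte(mean(covered), 0.9)
})
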