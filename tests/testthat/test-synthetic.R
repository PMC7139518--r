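test_that("generated percentages converge to the model profile", {
  truth <- cd8_controls()
  cp <- compartment_profile(steady_state(truth))
  cfg <- generator_config(1, n_pb_events = 1e6, n_csf_events = 1e6,
                          seed = 41)
  rec <- generate_patient(truth, cfg)
  se_pb <- 100 * sqrt(cp$pb_naive_frac * (1 - cp$pb_naive_frac) / 1e6)
  se_csf <- 100 * sqrt(cp$csf_naive_frac * (1 - cp$csf_naive_frac) / 1e6)
  expect_lt(abs(rec$pb_naive_pct - 100 * cp$pb_naive_frac), 3 * se_pb)
  expect_lt(abs(rec$csf_naive_pct - 100 * cp$csf_naive_frac), 3 * se_csf)
  # frozen expectations for the reference CD8 control profile
  expect_equal(100 * cp$pb_naive_frac, 89.42, tolerance = 1e-3)
  expect_equal(100 * cp$csf_naive_frac, 67.06, tolerance = 1e-3)
  # absolute counts scale with the compartment masses
  expect_equal(rec$pb_total_count, round(1e6 * cp$pb_mass))
  expect_equal(rec$csf_total_count, round(1e6 * cp$csf_mass))
})

test_that("records are reproducible given seed and patient index", {
  truth <- reference_rates("NK", "SuS")
  cfg <- generator_config(5, heterogeneity_sd = 0.1, seed = 42)
  r1 <- generate_patient(truth, cfg, patient_index = 3)
  r2 <- generate_patient(truth, cfg, patient_index = 3)
  expect_identical(r1, r2)
  cohort <- generate_cohort(truth, cfg)
  expect_identical(as.data.frame(cohort)[3, ], as.data.frame(r1[1, ]),
                   ignore_attr = TRUE)
  expect_false(identical(r1$pb_naive_pct,
                         generate_patient(truth, cfg, 4)$pb_naive_pct))
})

test_that("patient-to-patient spread matches the binomial noise model", {
  truth <- cd8_controls()
  cp <- compartment_profile(steady_state(truth))
  cohort <- generate_cohort(truth, generator_config(400, seed = 43))
  sd_emp <- sd(cohort$csf_naive_pct)
  sd_binom <- 100 * sqrt(cp$csf_naive_frac * (1 - cp$csf_naive_frac) / 200)
  expect_lt(abs(sd_emp - sd_binom) / sd_binom, 0.2)
  # logit-scale heterogeneity adds between-patient variance
  het <- generate_cohort(truth, generator_config(400, heterogeneity_sd = 0.3,
                                                 seed = 44))
  expect_gt(sd(het$pb_naive_pct), 2 * sd(cohort$pb_naive_pct))
})

test_that("cohorts carry their generating rates and reject empty sizes", {
  truth <- reference_rates("B", "controls")
  cohort <- generate_cohort(truth, generator_config(7, seed = 45))
  expect_s3_class(cohort, "lymph_cohort")
  expect_identical(nrow(cohort), 7L)
  expect_identical(attr(cohort, "generating_rates"), truth)
  expect_true(all(abs(cohort$pb_naive_pct + cohort$pb_diff_pct - 100) < 1e-9))
  expect_error(generator_config(0), "n_patients")
})

test_that("calibration on a near-noise-free cohort sits at the truth", {
  truth <- cd8_controls()
  cohort <- generate_cohort(truth, generator_config(
    20, n_pb_events = 1e6, n_csf_events = 1e6, seed = 46))
  v <- assemble_stage_vectors(cohort)
  # binomial noise floor at 1e6 events is ~1.5e-7; truth must sit on it
  expect_lt(stage_objective(truth, v), 1e-6)
  f <- fit_rates(v, options = calibration_options(multistart = 1))
  expect_equal(f$combos, identifiable_combinations(truth), tolerance = 1e-2)
})
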