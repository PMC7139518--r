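one_patient <- function() {
  data.frame(patient_id = "P1", group = "g", cell_type = "CD4",
             pb_naive_pct = 90, pb_diff_pct = 10,
             csf_naive_pct = 60, csf_diff_pct = 40,
             pb_total_count = 9990, csf_total_count = 10)
}

test_that("stage-vector assembly modes combine compartments correctly", {
  v <- assemble_stage_vectors(one_patient(), mode = "count_weighted")
  expect_equal(unname(v$vectors[1, ]), c(0.8991, 0.0006, 0.0999, 0.0004))
  expect_equal(sum(v$vectors), 1)

  v2 <- assemble_stage_vectors(one_patient(), mode = "fixed_weight",
                               csf_weight = 0.5)
  expect_equal(unname(v2$vectors[1, ]), c(0.45, 0.30, 0.05, 0.20))

  p <- one_patient()
  p$pb_total_count <- NULL
  expect_error(assemble_stage_vectors(p, mode = "count_weighted"),
               "count")
  p2 <- one_patient()
  p2$pb_naive_pct <- 120
  expect_error(assemble_stage_vectors(p2), "\\[0, 100\\]")

  joint <- data.frame(cell_type = "CD4",
                      pb_naive_pct = 45, pb_diff_pct = 5,
                      csf_naive_pct = 30, csf_diff_pct = 20)
  v3 <- assemble_stage_vectors(joint, mode = "joint")
  expect_equal(unname(v3$vectors[1, ]), c(0.45, 0.30, 0.05, 0.20))
  joint$csf_diff_pct <- 10 # four columns no longer sum to 100
  expect_error(assemble_stage_vectors(joint, mode = "joint"), "sum to 100")
})

test_that("least-squares objective matches direct expansion", {
  r <- cd8_controls()
  x <- as.numeric(steady_state(r))
  expect_equal(stage_objective(r, stage_vectors(x)), 0)
  # squared distance to the all-blood-naive corner, expanded by hand
  expect_equal(stage_objective(r, stage_vectors(c(1, 0, 0, 0))),
               0.02264183, tolerance = 1e-6)
  V <- stage_vectors(matrix(rep(c(1, 0, 0, 0), 5), nrow = 5, byrow = TRUE))
  expect_equal(stage_objective(r, V),
               stage_objective(r, stage_vectors(c(1, 0, 0, 0))))
})

test_that("fit achieves zero residual and recovers the identifiable combos", {
  R <- random_valid_rates(10, seed = 21)
  for (i in seq_len(nrow(R))) {
    truth <- rates_from_row(R[i, ])
    f <- fit_rates(stage_vectors(steady_state(truth)))
    expect_lt(f$objective, 1e-12)
    expect_equal(f$combos, identifiable_combinations(truth),
                 tolerance = 1e-6)
  }
})

test_that("fitting the all-blood-naive corner drives both stage-1 outflows to zero", {
  f <- fit_rates(stage_vectors(c(1, 0, 0, 0)))
  expect_lt(f$objective, 1e-12)
  expect_lt(f$rates$alpha1, 1e-8)
  expect_lt(f$rates$beta1, 1e-8)
})

test_that("calibration is deterministic", {
  v <- stage_vectors(steady_state(reference_rates("B", "RRMS_naive")))
  f1 <- fit_rates(v)
  f2 <- fit_rates(v)
  expect_identical(f1$rates, f2$rates)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$diagnostics, f2$diagnostics)
})

test_that("profile calibration with migration fixed recovers the differentiation rates", {
  cases <- list(list("CD8", "controls", "beta2", 19.7744),
                list("CD8", "SuS", "beta1", 22.3179),
                list("CD8", "RRMS_naive", "beta1", 12.6372))
  for (cs in cases) {
    truth <- reference_rates(cs[[1]], cs[[2]])
    v <- stage_vectors(steady_state(truth))
    pf <- profile_fit(v, fixed = c(alpha1 = truth$alpha1,
                                   alpha2 = truth$alpha2))
    expect_equal(100 * pf$rates[[cs[[3]]]], cs[[4]], tolerance = 1e-3)
    # closed-form brute-force oracle for the profiled problem
    x <- as.numeric(steady_state(truth))
    expect_equal(pf$rates$beta1, x[3] * (1 + truth$alpha2), tolerance = 1e-6)
    expect_equal(pf$rates$beta2, truth$alpha1 / x[2] - 1, tolerance = 1e-3)
  }
})

test_that("fully fixed profile fit evaluates the objective without searching", {
  r <- cd8_controls()
  v <- stage_vectors(c(1, 0, 0, 0))
  pf <- profile_fit(v, fixed = c(alpha1 = r$alpha1, alpha2 = r$alpha2,
                                 beta1 = r$beta1, beta2 = r$beta2))
  expect_identical(pf$n_starts, 0L)
  expect_equal(pf$objective, stage_objective(r, v))
})

test_that("identifiable combinations equal (1 - x1, x2, x3) of the steady state", {
  expect_equal(identifiable_combinations(transition_rates(0, 0, 0, 0)),
               c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(identifiable_combinations(cd8_controls()),
               c(s1 = 0.1071465, s2 = 0.0010090, s3 = 0.1056418),
               tolerance = 1e-5)
  R <- random_valid_rates(50, seed = 22)
  for (i in seq_len(nrow(R))) {
    r <- rates_from_row(R[i, ])
    x <- as.numeric(steady_state(r))
    expect_equal(unname(identifiable_combinations(r)),
                 c(1 - x[1], x[2], x[3]), tolerance = 1e-12)
  }
})

test_that("equivalent rate sets share the steady state and the objective", {
  r <- reference_rates("CD4", "controls")
  expect_identical(equivalent_rates(r, 0), r)

  r2 <- equivalent_rates(r, 2e-5)
  expect_equal(r2$alpha1, 0.00113389)
  expect_equal(r2$beta1, 0.0635874)
  expect_equal(r2$alpha2, 0.0005963, tolerance = 1e-4)
  expect_equal(r2$beta2, 0.0683096, tolerance = 1e-5)
  expect_lt(max(abs(as.numeric(steady_state(r2)) -
                      as.numeric(steady_state(r)))), 1e-12)
  # both parameter sets solve the same balance system
  expect_equal(solve_stage_system(r2), solve_stage_system(r),
               tolerance = 1e-12)

  expect_error(equivalent_rates(r, 1e-3), "feasible interval")

  v <- stage_vectors(c(1, 0, 0, 0))
  for (d in c(-2e-5, 1e-5, 5e-5))
    expect_equal(stage_objective(equivalent_rates(r, d), v),
                 stage_objective(r, v), tolerance = 1e-12)
})

test_that("combo errors shrink as flow-cytometry event counts grow", {
  truth <- cd8_controls()
  s_true <- identifiable_combinations(truth)
  rmse <- sapply(c(1, 4), function(scale) {
    errs <- sapply(1:25, function(rep) {
      co <- generate_cohort(truth, generator_config(
        40, n_pb_events = 10000 * scale, n_csf_events = 200 * scale,
        seed = 1000 * scale + rep))
      f <- fit_rates(assemble_stage_vectors(co),
                     options = calibration_options(multistart = 1))
      sum((f$combos - s_true)^2)
    })
    sqrt(mean(errs))
  })
  # quadrupling the event counts should roughly halve the error
  expect_lt(rmse[2], 0.75 * rmse[1])
  expect_gt(rmse[2], 0.3 * rmse[1])
})
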