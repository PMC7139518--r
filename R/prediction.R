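#' Infer a patient-specific blood differentiation rate from the PB profile
#'
#' Blood measurements alone cannot identify more than one free rate, so the
#' per-patient conditioning personalises only `beta1` (differentiation
#' within the blood) and keeps the cohort values of `alpha1`, `alpha2`,
#' `beta2`.  Solving the steady state for the value of `beta1` that makes
#' the model's blood naive fraction equal the patient's gives the closed
#' form
#' \deqn{\beta_1 = \frac{(1-p)(1-\alpha_1)}{p/(1+\alpha_2) + (1-p)},}
#' where \eqn{p} is the patient's naive fraction within peripheral blood.
#'
#' @param pb_naive_frac Patient's naive fraction within peripheral blood,
#'   in `[0, 1]`.
#' @param cohort_rates Cohort-calibrated [transition_rates()].
#' @return The inferred `beta1` (fraction in `[0, 1 - alpha1]`).
#' @export
infer_patient_beta1 <- function(pb_naive_frac, cohort_rates) {
  validate_rates(cohort_rates)
  p <- pb_naive_frac
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("pb_naive_frac must be a single number in [0, 1]", call. = FALSE)
  a1 <- cohort_rates$alpha1; a2 <- cohort_rates$alpha2
  b1 <- (1 - p) * (1 - a1) / (p / (1 + a2) + (1 - p))
  if (b1 < -1e-12 || b1 > 1 - a1 + 1e-12)
    stop(sprintf("inferred beta1 = %g outside the feasible range [0, %g]",
                 b1, 1 - a1), call. = FALSE)
  min(max(b1, 0), 1 - a1)
}

#' Predict a patient's CSF profile from blood measurements only
#'
#' Substitutes the patient-specific `beta1` inferred from the blood profile
#' (see [infer_patient_beta1()]) into the steady state with the cohort's
#' `alpha1`, `alpha2`, `beta2`, and returns the naive/differentiated split
#' within the CSF.
#'
#' @param pb_profile Numeric length-2 vector `(pb_naive_frac, pb_diff_frac)`
#'   summing to 1 (within `1e-6`), or a single naive fraction.
#' @param cohort_rates Cohort-calibrated [transition_rates()].
#' @return Object of class `"prediction_result"`: list with
#'   `csf_naive_frac`, `csf_diff_frac`, `patient_beta1`, and `NA` bootstrap
#'   bounds (`range_low`, `range_high`; filled by
#'   [bootstrap_prediction()]).
#' @examples
#' r <- reference_rates("CD8", "controls")
#' predict_csf(c(0.894199, 0.105801), r)
#' @export
predict_csf <- function(pb_profile, cohort_rates) {
  if (length(pb_profile) == 2L) {
    if (abs(sum(pb_profile) - 1) > 1e-6)
      stop(sprintf("pb_profile must sum to 1 (got %g)", sum(pb_profile)),
           call. = FALSE)
    p <- pb_profile[[1]]
  } else if (length(pb_profile) == 1L) {
    p <- pb_profile[[1]]
  } else stop("pb_profile must have length 1 or 2", call. = FALSE)

  b1 <- infer_patient_beta1(p, cohort_rates)
  pr <- transition_rates(cohort_rates$alpha1, cohort_rates$alpha2,
                         b1, cohort_rates$beta2,
                         cell_type = cohort_rates$cell_type,
                         group = cohort_rates$group)
  cp <- compartment_profile(steady_state(pr))
  structure(list(csf_naive_frac = cp$csf_naive_frac,
                 csf_diff_frac = cp$csf_diff_frac,
                 patient_beta1 = b1,
                 range_low = c(csf_naive_frac = NA_real_,
                               csf_diff_frac = NA_real_),
                 range_high = c(csf_naive_frac = NA_real_,
                                csf_diff_frac = NA_real_)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, digits = 4, ...) {
  cat(sprintf("Predicted CSF profile: naive %.*g / diff %.*g (patient beta1 = %.*g)\n",
              digits, x$csf_naive_frac, digits, x$csf_diff_frac,
              digits, x$patient_beta1))
  if (!anyNA(x$range_low))
    cat(sprintf("  95%% range, naive: [%.*g, %.*g]\n",
                digits, x$range_low[["csf_naive_frac"]],
                digits, x$range_high[["csf_naive_frac"]]))
  invisible(x)
}

#' Bootstrap ranges for blood-only CSF predictions
#'
#' Quantifies how much the CSF predictions depend on the particular training
#' cohort: the cohort is resampled with replacement `B` times, the rates are
#' recalibrated on each resample, and every new patient's CSF profile is
#' re-predicted under each refit.  Point estimates come from the full-cohort
#' fit; ranges are the 2.5th-97.5th percentiles across resamples
#' (percentile bootstrap, 95% by default).
#'
#' @param cohort Training cohort data frame (see [generate_cohort()],
#'   [read_cohort_csv()]).
#' @param pb_profiles New patients' blood profiles: numeric vector of naive
#'   fractions, or a two-column matrix `(pb_naive_frac, pb_diff_frac)`.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; the result is fully reproducible given the
#'   seed.  The caller's RNG state is restored on exit.
#' @param mode,csf_weight Passed to [assemble_stage_vectors()].
#' @param options [calibration_options()] used for the full fit and each
#'   refit.
#' @param resample Set `FALSE` to disable resampling (every replicate uses
#'   the full cohort; ranges collapse onto the point estimate) — mainly for
#'   testing.
#' @param level Coverage of the percentile interval (default 0.95).
#' @return A data frame with one row per new patient: point predictions
#'   (`csf_naive_frac`, `csf_diff_frac`, `patient_beta1`) and interval
#'   bounds (`csf_naive_low/high`, `csf_diff_low/high`).  The number of
#'   failed refits is attached as attribute `"n_failures"`; more than 50%
#'   failures is an error.
#' @export
bootstrap_prediction <- function(cohort, pb_profiles, B = 1000, seed = NULL,
                                 mode = "count_weighted", csf_weight = 0.001,
                                 options = calibration_options(),
                                 resample = TRUE, level = 0.95) {
  if (!is.numeric(B) || B < 1) stop("B must be >= 1", call. = FALSE)
  B <- as.integer(B)
  cohort <- as.data.frame(cohort)
  K <- nrow(cohort)
  if (K < 1L) stop("empty training cohort", call. = FALSE)
  P <- if (is.matrix(pb_profiles) || is.data.frame(pb_profiles))
    as.numeric(as.matrix(pb_profiles)[, 1]) else as.numeric(pb_profiles)
  n_new <- length(P)
  if (n_new < 1L) stop("no blood profiles to predict", call. = FALSE)

  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }

  full_fit <- fit_rates(assemble_stage_vectors(cohort, mode = mode,
                                               csf_weight = csf_weight),
                        options = options)
  point <- lapply(P, predict_csf, cohort_rates = full_fit$rates)

  draws_naive <- matrix(NA_real_, B, n_new)
  n_fail <- 0L
  for (b in seq_len(B)) {
    idx <- if (resample) sample.int(K, K, replace = TRUE) else seq_len(K)
    fb <- tryCatch(
      fit_rates(assemble_stage_vectors(cohort[idx, , drop = FALSE],
                                       mode = mode, csf_weight = csf_weight),
                options = options),
      error = function(e) NULL)
    if (is.null(fb)) { n_fail <- n_fail + 1L; next }
    draws_naive[b, ] <- vapply(P, function(p)
      predict_csf(p, fb$rates)$csf_naive_frac, numeric(1))
  }
  if (n_fail > B / 2)
    stop(sprintf("bootstrap refit failed in %d of %d resamples", n_fail, B),
         call. = FALSE)

  a <- (1 - level) / 2
  qs <- apply(draws_naive, 2, stats::quantile,
              probs = c(a, 1 - a), na.rm = TRUE, names = FALSE)
  out <- data.frame(
    pb_naive_frac = P,
    csf_naive_frac = vapply(point, `[[`, numeric(1), "csf_naive_frac"),
    csf_diff_frac = vapply(point, `[[`, numeric(1), "csf_diff_frac"),
    patient_beta1 = vapply(point, `[[`, numeric(1), "patient_beta1"),
    csf_naive_low = qs[1, ], csf_naive_high = qs[2, ],
    csf_diff_low = 1 - qs[2, ], csf_diff_high = 1 - qs[1, ])
  attr(out, "n_failures") <- n_fail
  attr(out, "B") <- B
  out
}
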