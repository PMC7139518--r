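#' Synthetic-cohort generator configuration
#'
#' Parameters of the flow-cytometry-like noise model used by
#' [generate_patient()] and [generate_cohort()].  The defaults emulate the
#' study setting the package targets: abundant blood material (10,000
#' gated events per blood sample) against low-cellularity CSF samples
#' (200 events), with absolute counts on a million-cell scale.
#'
#' @param n_patients Number of patients to generate (>= 1).
#' @param n_pb_events,n_csf_events Flow-cytometry events gated per
#'   compartment (defaults 10,000 and 200).
#' @param total_cells Scale for absolute per-compartment cell counts
#'   (default 1e6).
#' @param heterogeneity_sd Standard deviation of per-patient logit-scale
#'   jitter applied to each transition rate (default 0 = all patients share
#'   the generating rates).
#' @param seed Optional integer seed; each patient record is reproducible
#'   given the seed and the patient index.
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_patients, n_pb_events = 10000,
                             n_csf_events = 200, total_cells = 1e6,
                             heterogeneity_sd = 0, seed = NULL) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("n_patients must be >= 1", call. = FALSE)
  if (n_pb_events < 1 || n_csf_events < 1)
    stop("event counts must be >= 1", call. = FALSE)
  if (heterogeneity_sd < 0)
    stop("heterogeneity_sd must be >= 0", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_pb_events = as.integer(n_pb_events),
                 n_csf_events = as.integer(n_csf_events),
                 total_cells = total_cells,
                 heterogeneity_sd = heterogeneity_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "generator_config")
}

# per-patient deterministic sub-seed, kept well below 2^31
.patient_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483647)
}

# logit-scale jitter; rates exactly 0 or 1 have no interior neighbourhood
# and are left unjittered
.jitter_rates <- function(rates, sd) {
  v <- .rate_vec(rates)
  interior <- v > 0 & v < 1
  v[interior] <- stats::plogis(stats::qlogis(v[interior]) +
                                 stats::rnorm(sum(interior), 0, sd))
  v
}

#' Generate one synthetic patient record
#'
#' Draws a flow-cytometry-like record from known transition rates: the
#' generating rates are optionally jittered per patient on the logit scale,
#' the implied compartment profile is computed, and the observed naive
#' percentages are obtained by binomial sampling of the gated events in
#' each compartment (`Binomial(n_pb_events, pb_naive_frac)` and
#' `Binomial(n_csf_events, csf_naive_frac)`).  Absolute compartment counts
#' are `round(total_cells * compartment mass)`.
#'
#' @param rates Generating [transition_rates()].
#' @param config A [generator_config()].
#' @param patient_index Positive integer identifying the patient; together
#'   with `config$seed` it determines the record exactly.
#' @return One-row data frame with columns `patient_id`, `group`,
#'   `cell_type`, `pb_naive_pct`, `pb_diff_pct`, `csf_naive_pct`,
#'   `csf_diff_pct`, `pb_total_count`, `csf_total_count`.
#' @export
generate_patient <- function(rates, config, patient_index = 1L) {
  validate_rates(rates)
  if (!inherits(config, "generator_config"))
    stop("`config` must be a generator_config object", call. = FALSE)
  if (patient_index < 1) stop("patient_index must be >= 1", call. = FALSE)

  if (!is.null(config$seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(.patient_seed(config$seed, patient_index))
  }

  v <- .rate_vec(rates)
  if (config$heterogeneity_sd > 0) {
    for (try in 1:100) {
      v <- .jitter_rates(rates, config$heterogeneity_sd)
      if (v[["alpha1"]] + v[["beta1"]] <= 1) break
      if (try == 100)
        stop("could not draw feasible jittered rates (alpha1 + beta1 <= 1) in 100 attempts",
             call. = FALSE)
    }
  }
  x <- .stage_vec(v)
  cp <- compartment_profile(x)

  pb_ev <- stats::rbinom(1, config$n_pb_events, cp$pb_naive_frac)
  csf_ev <- stats::rbinom(1, config$n_csf_events, cp$csf_naive_frac)
  pb_naive_pct <- 100 * pb_ev / config$n_pb_events
  csf_naive_pct <- 100 * csf_ev / config$n_csf_events

  data.frame(
    patient_id = sprintf("P%04d", as.integer(patient_index)),
    group = rates$group, cell_type = rates$cell_type,
    pb_naive_pct = pb_naive_pct, pb_diff_pct = 100 - pb_naive_pct,
    csf_naive_pct = csf_naive_pct, csf_diff_pct = 100 - csf_naive_pct,
    pb_total_count = round(config$total_cells * cp$pb_mass),
    csf_total_count = round(config$total_cells * cp$csf_mass))
}

#' Generate a synthetic cohort
#'
#' @inheritParams generate_patient
#' @return Data frame of class `c("lymph_cohort", "data.frame")` with
#'   `config$n_patients` rows (see [generate_patient()] for columns) and
#'   the generating rates attached as attribute `"generating_rates"`.
#' @examples
#' rates <- reference_rates("CD8", "controls")
#' cohort <- generate_cohort(rates, generator_config(5, seed = 1))
#' head(cohort)
#' @export
generate_cohort <- function(rates, config) {
  validate_rates(rates)
  if (!inherits(config, "generator_config"))
    stop("`config` must be a generator_config object", call. = FALSE)
  recs <- lapply(seq_len(config$n_patients), function(i)
    generate_patient(rates, config, patient_index = i))
  out <- do.call(rbind, recs)
  attr(out, "generating_rates") <- rates
  class(out) <- c("lymph_cohort", "data.frame")
  out
}
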