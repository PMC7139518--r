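#' Event-level stochastic simulation of the four-stage trafficking model
#'
#' Independent verification oracle for [steady_state()].  Cells enter the
#' system as a Poisson stream with intensity `birth_rate` and are assigned
#' at birth to the CSF-naive stage with probability `alpha1`, to the
#' PB-differentiated stage with probability `beta1`, and to the PB-naive
#' stage otherwise (the stationary balance routes the stage-1 outflows in
#' proportion to the source, so the assignment happens at entry).  Each cell
#' then evolves independently: CSF-naive cells differentiate (move to
#' CSF-differentiated) at rate `beta2`, PB-differentiated cells migrate to
#' CSF-differentiated at rate `alpha2`, and every cell is cleared (dies) at
#' rate 1 in every stage.  This is the unique simple linear birth-death
#' system whose expected stationary occupancy, divided by `birth_rate`,
#' equals the model's stage probabilities.
#'
#' Because cells are independent, the process is simulated exactly by
#' drawing each cell's birth time, stage assignment and exponential
#' holding times; no event queue is needed and the event stream is fully
#' reproducible under a fixed seed.
#'
#' @param rates A [transition_rates()] object.
#' @param birth_rate Cells entering per unit time (Lambda, > 0).
#' @param horizon Simulated time span (> `burn_in`).
#' @param burn_in Initial time discarded from the occupancy averages
#'   (default 0).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param n_batches Number of equal-length batches used for the batch-means
#'   Monte Carlo standard errors (default 10).
#' @return Object of class `"simulation_result"`: list with
#'   `mean_occupancy` and `standard_errors` (time-averaged cell counts per
#'   stage over the post-burn-in window), `stage_estimate` and
#'   `se_estimate` (the same divided by `birth_rate`, i.e. estimates of the
#'   stage probabilities), and the event tallies `births`, `deaths`,
#'   `alive` (at the horizon), which always satisfy
#'   `births == deaths + alive`.
#' @examples
#' r <- reference_rates("CD8", "controls")
#' s <- simulate_trafficking(r, birth_rate = 500, horizon = 50,
#'                           burn_in = 5, seed = 1)
#' rbind(estimate = s$stage_estimate, exact = as.numeric(steady_state(r)))
#' @export
simulate_trafficking <- function(rates, birth_rate, horizon, burn_in = 0,
                                 seed = NULL, n_batches = 10) {
  validate_rates(rates)
  if (!is.numeric(birth_rate) || birth_rate <= 0)
    stop("birth_rate must be > 0", call. = FALSE)
  if (!is.numeric(horizon) || horizon <= 0)
    stop("horizon must be > 0", call. = FALSE)
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in >= horizon)
    stop("need horizon > burn_in >= 0", call. = FALSE)
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  a1 <- rates$alpha1; a2 <- rates$alpha2
  b1 <- rates$beta1; b2 <- rates$beta2

  N <- stats::rpois(1, birth_rate * horizon)
  t0 <- stats::runif(N, 0, horizon)
  u <- stats::runif(N)
  stage0 <- ifelse(u < a1, 2L, ifelse(u < a1 + b1, 3L, 1L))

  # exit rate and onward-transition probability of the entry stage
  exit_rate <- c(1, 1 + b2, 1 + a2)[stage0]
  p_move <- c(0, b2 / (1 + b2), a2 / (1 + a2))[stage0]
  dwell <- stats::rexp(N, exit_rate)
  moved <- stats::runif(N) < p_move
  t1 <- t0 + dwell
  dwell4 <- stats::rexp(sum(moved), 1)
  death <- t1
  death[moved] <- t1[moved] + dwell4

  seg_stage <- c(stage0, rep.int(4L, sum(moved)))
  seg_lo <- c(t0, t1[moved])
  seg_hi <- c(t1, death[moved])

  window_occ <- function(lo, hi) {
    ov <- pmax(0, pmin(seg_hi, hi) - pmax(seg_lo, lo))
    occ <- vapply(1:4, function(s) sum(ov[seg_stage == s]), numeric(1))
    occ / (hi - lo)
  }
  mean_occ <- window_occ(burn_in, horizon)

  edges <- seq(burn_in, horizon, length.out = n_batches + 1)
  batch <- t(vapply(seq_len(n_batches),
                    function(i) window_occ(edges[i], edges[i + 1]),
                    numeric(4)))
  se <- apply(batch, 2, stats::sd) / sqrt(n_batches)

  deaths <- sum(death <= horizon)
  names(mean_occ) <- names(se) <- .stage_names
  structure(list(mean_occupancy = mean_occ, standard_errors = se,
                 stage_estimate = mean_occ / birth_rate,
                 se_estimate = se / birth_rate,
                 births = N, deaths = deaths, alive = N - deaths,
                 birth_rate = birth_rate, horizon = horizon,
                 burn_in = burn_in, n_batches = n_batches),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, digits = 4, ...) {
  cat(sprintf("Stochastic trafficking simulation: %d births, %d deaths, %d alive\n",
              x$births, x$deaths, x$alive))
  m <- rbind(stage_estimate = x$stage_estimate, se = x$se_estimate)
  print(signif(m, digits))
  invisible(x)
}
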