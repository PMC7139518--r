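#' Assemble per-patient four-stage probability vectors from a cohort
#'
#' Combines each patient's within-compartment percentages into a single
#' probability vector over the four stages (PB/naive, CSF/naive, PB/diff,
#' CSF/diff).  The within-compartment splits only determine the vector up to
#' the relative mass of the two compartments, so a weighting mode is needed:
#'
#' * `"count_weighted"` — compartment masses proportional to the absolute
#'   cell counts `pb_total_count` / `csf_total_count` (required);
#' * `"fixed_weight"` — every patient gets the same CSF mass `csf_weight`;
#' * `"joint"` — the four percentage columns already form a joint
#'   distribution summing to 100 across all four stages.
#'
#' @param cohort A cohort data frame as returned by [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param mode Assembly mode, see above.  Default `"count_weighted"`.
#' @param csf_weight CSF compartment mass used by `"fixed_weight"`
#'   (default 0.001, a stated assumption reflecting the roughly
#'   thousand-fold lower CSF cellularity, not an estimate).
#' @return Object of class `"cohort_vectors"`: list with `vectors` (K x 4
#'   matrix, rows summing to 1), `cell_type`, `assembly_mode`.
#' @export
assemble_stage_vectors <- function(cohort,
                                   mode = c("count_weighted", "fixed_weight",
                                            "joint"),
                                   csf_weight = 0.001) {
  mode <- match.arg(mode)
  cohort <- as.data.frame(cohort)
  if (nrow(cohort) < 1L) stop("empty cohort", call. = FALSE)
  req <- c("pb_naive_pct", "pb_diff_pct", "csf_naive_pct", "csf_diff_pct")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  P <- as.matrix(cohort[req])
  if (any(!is.finite(P)) || any(P < 0) || any(P > 100))
    stop("percentages must be finite and within [0, 100]", call. = FALSE)

  if (mode == "count_weighted") {
    if (!all(c("pb_total_count", "csf_total_count") %in% names(cohort)) ||
        anyNA(cohort$pb_total_count) || anyNA(cohort$csf_total_count))
      stop(paste("count_weighted assembly requires pb_total_count and",
                 "csf_total_count for every patient; use mode =",
                 "'fixed_weight' when absolute counts are unavailable"),
           call. = FALSE)
    tot <- cohort$pb_total_count + cohort$csf_total_count
    if (any(tot <= 0)) stop("nonpositive total cell count", call. = FALSE)
    w_csf <- cohort$csf_total_count / tot
  } else if (mode == "fixed_weight") {
    if (!is.numeric(csf_weight) || csf_weight <= 0 || csf_weight >= 1)
      stop("csf_weight must lie strictly between 0 and 1", call. = FALSE)
    w_csf <- rep(csf_weight, nrow(cohort))
  } else { # joint
    s <- rowSums(P)
    if (any(abs(s - 100) > 0.5))
      stop("joint mode requires the four percentages to sum to 100 per patient",
           call. = FALSE)
    V <- P / s
    return(.cohort_vectors(V[, c(1, 3, 2, 4), drop = FALSE], cohort, mode))
  }
  w_pb <- 1 - w_csf
  V <- cbind(w_pb * P[, 1], w_csf * P[, 3], w_pb * P[, 2], w_csf * P[, 4])
  V <- V / rowSums(V)
  .cohort_vectors(V, cohort, mode)
}

.cohort_vectors <- function(V, cohort, mode) {
  colnames(V) <- .stage_names
  ct <- unique(as.character(cohort$cell_type))
  structure(list(vectors = V,
                 cell_type = if (length(ct) == 1L) ct else NA_character_,
                 assembly_mode = mode),
            class = "cohort_vectors")
}

# coerce a bare matrix of stage vectors (rows sum to 1) for programmatic use
#' Build a cohort-vector set directly from a matrix
#'
#' Lower-level companion to [assemble_stage_vectors()] for callers that
#' already hold four-stage probability vectors (e.g. noise-free vectors from
#' [steady_state()]).
#'
#' @param x Numeric K x 4 matrix (or length-4 vector), rows nonnegative and
#'   summing to 1 within `1e-9`.
#' @param cell_type Optional lineage label.
#' @return A `"cohort_vectors"` object.
#' @export
stage_vectors <- function(x, cell_type = NA_character_) {
  V <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  if (ncol(V) != 4L || any(!is.finite(V)) || any(V < -1e-12))
    stop("stage vectors must be nonnegative with four columns", call. = FALSE)
  if (any(abs(rowSums(V) - 1) > 1e-9))
    stop("each stage vector must sum to 1 (within 1e-9)", call. = FALSE)
  colnames(V) <- .stage_names
  structure(list(vectors = V, cell_type = as.character(cell_type),
                 assembly_mode = "direct"),
            class = "cohort_vectors")
}

#' Mean squared deviation between model and measured stage vectors
#'
#' The calibration objective: \eqn{\frac{1}{K}\sum_k \|X(\alpha,\beta) -
#' X_k\|^2}, where \eqn{X(\alpha,\beta)} is the model's stationary stage
#' distribution and \eqn{X_k} the measured vectors.
#'
#' @param rates A [transition_rates()] object.
#' @param vectors A `"cohort_vectors"` object.
#' @return Nonnegative scalar.
#' @export
stage_objective <- function(rates, vectors) {
  validate_rates(rates)
  V <- .check_vectors(vectors)
  x <- .stage_vec(.rate_vec(rates))
  mean(rowSums(sweep(V, 2, x)^2))
}

.check_vectors <- function(vectors) {
  if (!inherits(vectors, "cohort_vectors"))
    stop("`vectors` must be a cohort_vectors object (see assemble_stage_vectors)",
         call. = FALSE)
  V <- vectors$vectors
  if (nrow(V) < 1L) stop("empty cohort", call. = FALSE)
  V
}

#' Calibration options
#'
#' @param tolerance Requested objective-decrease convergence threshold.  The
#'   default `1e-16` is mapped to the tightest tolerance the optimizer can
#'   honour in double precision (`factr = max(1, tolerance / eps)` for
#'   L-BFGS-B).
#' @param multistart Number of deterministic start values per free rate
#'   (equispaced on `[0.1, 0.9]`; the default 3 gives 0.1, 0.5, 0.9).  The
#'   centre of the constraint set is always added as an extra start.
#' @param fixed Optional named numeric vector holding a subset of
#'   `c("alpha1","alpha2","beta1","beta2")` at fixed values (profile
#'   calibration).
#' @return List of class `"calibration_options"`.
#' @export
calibration_options <- function(tolerance = 1e-16, multistart = 3,
                                fixed = NULL) {
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0", call. = FALSE)
  if (!is.numeric(multistart) || multistart < 1)
    stop("multistart must be >= 1", call. = FALSE)
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% .rate_names))
      stop("`fixed` must be named with a subset of: ",
           paste(.rate_names, collapse = ", "), call. = FALSE)
    if (any(fixed < 0 | fixed > 1))
      stop("fixed rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(tolerance = tolerance, multistart = as.integer(multistart),
                 fixed = fixed),
            class = "calibration_options")
}

# gradient of sum((X(r) - m)^2) wrt the four rates, r in canonical order
.objective_gradient <- function(r, m) {
  a1 <- r[1]; a2 <- r[2]; b1 <- r[3]; b2 <- r[4]
  x <- .stage_vec(r)
  d <- x - m
  g1 <- 2 * sum(d * c(-1, 1 / (1 + b2), 0, b2 / (1 + b2)))
  g2 <- 2 * sum(d * c(0, 0, -b1 / (1 + a2)^2, b1 / (1 + a2)^2))
  g3 <- 2 * sum(d * c(-1, 0, 1 / (1 + a2), a2 / (1 + a2)))
  g4 <- 2 * sum(d * c(0, -a1 / (1 + b2)^2, 0, a1 / (1 + b2)^2))
  c(g1, g2, g3, g4)
}

#' Calibrate transition rates by constrained least squares
#'
#' Minimises the unweighted mean squared deviation between the model's
#' stationary stage distribution and the measured cohort vectors over the
#' four rates, subject to the box `[0, 1]` on each rate and the feasibility
#' constraint `alpha1 + beta1 <= 1`.  Bounded local minimisation
#' (L-BFGS-B with analytic gradient; the feasibility constraint enters as a
#' steep quadratic penalty, with a final projection) is run from every point
#' of a deterministic multistart grid; the best objective wins, ties broken
#' by the smaller L2 norm of the rate vector, then by grid order — the
#' result is fully deterministic.
#'
#' The steady state depends on the four rates only through three
#' identifiable combinations, \eqn{s_1 = \alpha_1+\beta_1},
#' \eqn{s_2 = \alpha_1/(1+\beta_2)}, \eqn{s_3 = \beta_1/(1+\alpha_2)}, so the
#' raw rates at the optimum are one point on an equal-objective family.  The
#' result reports the combinations (which are identified) and the feasible
#' width of that family; see [equivalent_rates()].
#'
#' @param vectors A `"cohort_vectors"` object.
#' @param options A [calibration_options()] object.
#' @param fixed Optional named vector of rates to hold fixed (overrides
#'   `options$fixed`); see [profile_fit()].
#' @return Object of class `"calibration_result"`: list with `rates`,
#'   `objective`, `combos` (s1, s2, s3), `converged`, `n_starts`,
#'   `family_width` (and `family_interval`), `fixed`, `diagnostics`
#'   (per-start data frame).
#' @examples
#' v <- stage_vectors(steady_state(reference_rates("CD8", "controls")))
#' fit_rates(v)
#' @export
fit_rates <- function(vectors, options = calibration_options(),
                      fixed = options$fixed) {
  V <- .check_vectors(vectors)
  m <- colMeans(V)
  const <- mean(rowSums(sweep(V, 2, m)^2)) # objective = |x-m|^2 + const

  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% .rate_names))
      stop("`fixed` must be named with a subset of: ",
           paste(.rate_names, collapse = ", "), call. = FALSE)
    fixed <- fixed[!duplicated(names(fixed))]
  }
  free <- setdiff(.rate_names, names(fixed))
  full_par <- function(th) {
    r <- numeric(4); names(r) <- .rate_names
    r[names(fixed)] <- fixed
    r[free] <- th
    r
  }

  if (length(free) == 0L) {
    r <- full_par(numeric(0))
    rt <- .as_rates(r, vectors)
    obj <- stage_objective(rt, vectors)
    return(.calibration_result(rt, obj, converged = TRUE, n_starts = 0L,
                               fixed = fixed, diagnostics = NULL))
  }

  pen_w <- 1e6
  fn <- function(th) {
    r <- full_par(th)
    x <- .stage_vec(r)
    sum((x - m)^2) + const + pen_w * max(0, r[1] + r[3] - 1)^2
  }
  free_idx <- match(free, .rate_names)
  gr <- function(th) {
    r <- full_par(th)
    g <- .objective_gradient(r, m)
    v <- max(0, r[1] + r[3] - 1)
    g[1] <- g[1] + 2 * pen_w * v
    g[3] <- g[3] + 2 * pen_w * v
    g[free_idx]
  }

  gvals <- if (options$multistart == 1L) 0.1 else
    seq(0.1, 0.9, length.out = options$multistart)
  starts <- as.matrix(expand.grid(rep(list(gvals), length(free)),
                                  KEEP.OUT.ATTRS = FALSE))
  starts <- rbind(starts, rep(0.5, length(free)))
  factr <- max(1, options$tolerance / .Machine$double.eps)

  n <- nrow(starts)
  res_par <- matrix(NA_real_, n, 4, dimnames = list(NULL, .rate_names))
  res_obj <- rep(NA_real_, n)
  res_conv <- rep(NA_integer_, n)
  res_msg <- character(n)
  for (i in seq_len(n)) {
    o <- tryCatch(
      stats::optim(starts[i, ], fn, gr, method = "L-BFGS-B",
                   lower = 0, upper = 1,
                   control = list(factr = factr, pgtol = 0, maxit = 1000L)),
      error = function(e) e)
    if (inherits(o, "error")) {
      res_msg[i] <- conditionMessage(o)
      next
    }
    r <- full_par(o$par)
    # project back if the penalized optimum overshoots the constraint
    s <- r[["alpha1"]] + r[["beta1"]]
    if (s > 1) {
      r[["alpha1"]] <- r[["alpha1"]] / s
      r[["beta1"]] <- r[["beta1"]] / s
    }
    r <- pmin(pmax(r, 0), 1)
    res_par[i, ] <- r
    res_obj[i] <- sum((.stage_vec(r) - m)^2) + const
    res_conv[i] <- o$convergence
    res_msg[i] <- if (is.null(o$message)) "" else o$message
  }

  ok <- which(!is.na(res_obj))
  if (length(ok) == 0L) {
    diag <- data.frame(start = seq_len(n), objective = res_obj,
                       convergence = res_conv, message = res_msg)
    stop(paste0("calibration failed to converge from every start (",
                n, " starts); see attached diagnostics"),
         call. = FALSE)
  }
  best <- min(res_obj[ok])
  tie_tol <- 1e-12 * max(1, abs(best)) + 1e-15
  cand <- ok[res_obj[ok] <= best + tie_tol]
  norms <- sqrt(rowSums(res_par[cand, , drop = FALSE]^2))
  cand <- cand[order(norms, cand)] # smallest L2 norm, then grid order
  pick <- cand[1]

  rt <- .as_rates(res_par[pick, ], vectors)
  diagnostics <- data.frame(start = seq_len(n), res_par,
                            objective = res_obj, convergence = res_conv,
                            message = res_msg)
  .calibration_result(rt, res_obj[pick],
                      converged = any(res_conv[ok] == 0L),
                      n_starts = n, fixed = fixed, diagnostics = diagnostics)
}

.as_rates <- function(r, vectors) {
  transition_rates(r[["alpha1"]], r[["alpha2"]], r[["beta1"]], r[["beta2"]],
                   cell_type = vectors$cell_type)
}

.calibration_result <- function(rates, objective, converged, n_starts,
                                fixed, diagnostics) {
  fam <- .family_interval(rates)
  structure(list(rates = rates, objective = objective,
                 combos = identifiable_combinations(rates),
                 converged = converged, n_starts = n_starts,
                 family_interval = fam,
                 family_width = diff(fam),
                 fixed = fixed, diagnostics = diagnostics),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, digits = 6, ...) {
  cat("Constrained least-squares calibration\n")
  cat(sprintf("  objective (mean squared deviation): %.6g\n", x$objective))
  cat("  rates (one representative of the equal-objective family):\n")
  print(signif(.rate_vec(x$rates), digits))
  cat("  identifiable combinations:\n")
  print(signif(x$combos, digits))
  cat(sprintf("  family width (feasible delta interval): %.3g\n",
              x$family_width))
  cat(sprintf("  starts: %d, converged: %s\n", x$n_starts, x$converged))
  invisible(x)
}

#' Profile calibration with a subset of rates fixed
#'
#' Runs [fit_rates()] over the free rates only, holding the named subset at
#' given values.  With both migration rates fixed the reduced problem is
#' well posed: noise-free data then determine the two differentiation rates
#' exactly (\eqn{\beta_1 = x_3 (1+\alpha_2)}, \eqn{\beta_2 = \alpha_1/x_2 - 1}).
#'
#' @inheritParams fit_rates
#' @param fixed Named numeric vector; names among
#'   `c("alpha1","alpha2","beta1","beta2")`.
#' @return A `"calibration_result"`.
#' @examples
#' truth <- reference_rates("CD8", "SuS")
#' v <- stage_vectors(steady_state(truth))
#' profile_fit(v, fixed = c(alpha1 = truth$alpha1, alpha2 = truth$alpha2))
#' @export
profile_fit <- function(vectors, fixed, options = calibration_options()) {
  fit_rates(vectors, options = options, fixed = fixed)
}

#' Identifiable parameter combinations
#'
#' The stationary stage distribution determines exactly three functions of
#' the four rates: \eqn{s_1 = \alpha_1 + \beta_1 = 1 - x_1},
#' \eqn{s_2 = \alpha_1/(1+\beta_2) = x_2} and
#' \eqn{s_3 = \beta_1/(1+\alpha_2) = x_3}.  Any two rate sets sharing these
#' three values produce an identical steady state.
#'
#' @param rates A [transition_rates()] object.
#' @return Named numeric vector `c(s1, s2, s3)`.
#' @export
identifiable_combinations <- function(rates) {
  validate_rates(rates)
  c(s1 = rates$alpha1 + rates$beta1,
    s2 = rates$alpha1 / (1 + rates$beta2),
    s3 = rates$beta1 / (1 + rates$alpha2))
}

# feasible delta interval of the equal-steady-state family around `rates`
.family_interval <- function(rates) {
  x <- .stage_vec(.rate_vec(rates))
  a1 <- rates$alpha1; b1 <- rates$beta1
  if (x[2] <= 0 || x[3] <= 0) return(c(lower = 0, upper = 0))
  lo <- max(x[2] - a1, b1 - 2 * x[3], -a1)
  hi <- min(b1 - x[3], 2 * x[2] - a1, 1 - a1)
  if (hi < lo) c(lower = 0, upper = 0) else c(lower = lo, upper = hi)
}

#' Construct an equivalent rate set with identical steady state
#'
#' Constructive witness of the model's structural non-identifiability:
#' shifts `delta` of probability mass from the blood differentiation route
#' to the naive migration route (\eqn{\alpha_1' = \alpha_1 + \delta},
#' \eqn{\beta_1' = \beta_1 - \delta}) and rescales the downstream rates
#' (\eqn{\alpha_2' = \beta_1'/x_3 - 1}, \eqn{\beta_2' = \alpha_1'/x_2 - 1})
#' so that the stationary stage distribution is unchanged.
#'
#' @param rates A [transition_rates()] object with `alpha1 > 0` and
#'   `beta1 > 0` (otherwise only `delta = 0` is feasible).
#' @param delta Mass shift; must lie in the feasible interval for which all
#'   four adjusted rates stay in `[0, 1]` (reported by
#'   `fit_rates()$family_interval`).
#' @return A [transition_rates()] object with a steady state identical to
#'   the input's.
#' @examples
#' r <- reference_rates("CD4", "controls")
#' r2 <- equivalent_rates(r, 2e-5)
#' max(abs(steady_state(r2) - steady_state(r))) # ~1e-17
#' @export
equivalent_rates <- function(rates, delta) {
  validate_rates(rates)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta))
    stop("`delta` must be a single finite number", call. = FALSE)
  if (delta == 0) return(rates)
  x <- .stage_vec(.rate_vec(rates))
  if (x[2] <= 0 || x[3] <= 0)
    stop("equal-steady-state family is degenerate (a CSF-naive or PB-diff stage is empty); only delta = 0 is feasible",
         call. = FALSE)
  fam <- .family_interval(rates)
  if (delta < fam["lower"] - 1e-15 || delta > fam["upper"] + 1e-15)
    stop(sprintf("delta = %g outside the feasible interval [%g, %g]: an adjusted rate would leave [0, 1]",
                 delta, fam["lower"], fam["upper"]), call. = FALSE)
  a1 <- rates$alpha1 + delta
  b1 <- rates$beta1 - delta
  transition_rates(a1, b1 / x[3] - 1, b1, a1 / x[2] - 1,
                   cell_type = rates$cell_type, group = rates$group)
}
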