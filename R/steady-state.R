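# Stage ordering used everywhere:
#   1 = PB/naive, 2 = CSF/naive, 3 = PB/differentiated, 4 = CSF/differentiated
.stage_names <- c("pb_naive", "csf_naive", "pb_diff", "csf_diff")

# closed-form stationary stage probabilities for a rate vector
# r = c(alpha1, alpha2, beta1, beta2); csf_rate switches which differentiation
# rate drives the CSF naive balance (see steady_state).
.stage_vec <- function(r, csf_rate = "beta2") {
  bc <- if (csf_rate == "beta2") r[[4]] else r[[3]]
  x1 <- 1 - r[[1]] - r[[3]]
  x2 <- r[[1]] / (1 + bc)
  x3 <- r[[3]] / (1 + r[[2]])
  x4 <- bc * x2 + r[[2]] * x3
  c(pb_naive = x1, csf_naive = x2, pb_diff = x3, csf_diff = x4)
}

#' Linear balance system of the four-stage model
#'
#' Builds the 4x4 coefficient matrix and right-hand side whose solution is
#' the stationary stage distribution, with the total cell mass normalised to
#' one.  The balance equations are (stage order: PB/naive, CSF/naive,
#' PB/differentiated, CSF/differentiated):
#' \deqn{x_1 = 1 - \alpha_1 - \beta_1}
#' \deqn{(1 + \beta_2)\, x_2 = \alpha_1}
#' \deqn{(1 + \alpha_2)\, x_3 = \beta_1}
#' \deqn{x_4 = \beta_2 x_2 + \alpha_2 x_3}
#' All matrix and right-hand-side entries depend linearly on the rates, and
#' the matrix is invertible for any nonnegative rates (its determinant is
#' \eqn{(1+\beta_2)(1+\alpha_2)}).
#'
#' @inheritParams steady_state
#' @return A list of class `"stage_system"` with elements `matrix` (4x4) and
#'   `rhs` (length 4), both with stage-named dimnames.
#' @seealso [steady_state()] for the closed-form solution.
#' @export
stage_system <- function(rates, csf_rate = c("beta2", "beta1")) {
  validate_rates(rates)
  csf_rate <- match.arg(csf_rate)
  bc <- if (csf_rate == "beta2") rates$beta2 else rates$beta1
  A <- rbind(c(1, 0, 0, 0),
             c(0, 1 + bc, 0, 0),
             c(0, 0, 1 + rates$alpha2, 0),
             c(0, -bc, -rates$alpha2, 1))
  dimnames(A) <- list(.stage_names, .stage_names)
  b <- c(1 - rates$alpha1 - rates$beta1, rates$alpha1, rates$beta1, 0)
  names(b) <- .stage_names
  structure(list(matrix = A, rhs = b, csf_rate = csf_rate),
            class = "stage_system")
}

#' Stationary stage distribution
#'
#' Closed-form stationary probabilities of the four cell stages
#' \eqn{(x_1, x_2, x_3, x_4)} = (PB/naive, CSF/naive, PB/differentiated,
#' CSF/differentiated) implied by a set of transition rates:
#' \deqn{x_1 = 1 - \alpha_1 - \beta_1,\quad
#'       x_2 = \frac{\alpha_1}{1+\beta_2},\quad
#'       x_3 = \frac{\beta_1}{1+\alpha_2},\quad
#'       x_4 = \beta_2 x_2 + \alpha_2 x_3.}
#' The probabilities are nonnegative for any feasible rates and sum to one
#' analytically.
#'
#' @param rates A [transition_rates()] object.
#' @param csf_rate Which differentiation rate governs the CSF naive balance:
#'   `"beta2"` (default; differentiation within the CSF proceeds at its own
#'   rate, matching the compartment semantics of the stage diagram) or
#'   `"beta1"` (a model variant that reuses the blood differentiation rate in
#'   the CSF balance, kept for sensitivity analysis).  Total mass is
#'   conserved under either variant.
#' @return An object of class `"stage_distribution"`: a named numeric vector
#'   of the four stage probabilities, with the generating rates attached as
#'   attribute `"rates"`.
#' @examples
#' steady_state(reference_rates("CD8", "controls"))
#' @export
steady_state <- function(rates, csf_rate = c("beta2", "beta1")) {
  validate_rates(rates)
  csf_rate <- match.arg(csf_rate)
  x <- .stage_vec(.rate_vec(rates), csf_rate)
  structure(x, class = "stage_distribution", rates = rates,
            csf_rate = csf_rate)
}

#' @export
print.stage_distribution <- function(x, digits = 6, ...) {
  cat("Stationary stage distribution (PB/CSF x naive/differentiated)\n")
  print(signif(unclass(x)[1:4], digits))
  invisible(x)
}

#' Per-compartment naive/differentiated profile
#'
#' Renormalises a four-stage distribution within each compartment, matching
#' how flow-cytometry results are reported: the naive/differentiated split
#' within peripheral blood, the split within CSF, and the fraction of all
#' modelled cells found in each compartment.
#'
#' @param dist A [steady_state()] result, or any numeric vector of four
#'   nonnegative stage probabilities in the order (PB/naive, CSF/naive,
#'   PB/differentiated, CSF/differentiated).
#' @return An object of class `"compartment_profile"`: a list with
#'   `pb_naive_frac`, `pb_diff_frac`, `csf_naive_frac`, `csf_diff_frac`,
#'   `pb_mass`, `csf_mass`.
#' @examples
#' compartment_profile(steady_state(reference_rates("NK", "controls")))
#' @export
compartment_profile <- function(dist) {
  x <- as.numeric(dist)
  if (length(x) != 4L || any(!is.finite(x)) || any(x < -1e-12))
    stop("`dist` must be four nonnegative stage probabilities", call. = FALSE)
  pb_mass <- x[1] + x[3]
  csf_mass <- x[2] + x[4]
  if (pb_mass <= 0)
    stop("degenerate input: peripheral-blood compartment has zero mass",
         call. = FALSE)
  if (csf_mass <= 0)
    stop("degenerate input: CSF compartment has zero mass", call. = FALSE)
  structure(list(
    pb_naive_frac = x[1] / pb_mass, pb_diff_frac = x[3] / pb_mass,
    csf_naive_frac = x[2] / csf_mass, csf_diff_frac = x[4] / csf_mass,
    pb_mass = pb_mass, csf_mass = csf_mass),
    class = "compartment_profile")
}

#' @export
print.compartment_profile <- function(x, digits = 4, ...) {
  cat(sprintf("PB : naive %.*g / diff %.*g  (mass %.*g)\n",
              digits, x$pb_naive_frac, digits, x$pb_diff_frac,
              digits, x$pb_mass))
  cat(sprintf("CSF: naive %.*g / diff %.*g  (mass %.*g)\n",
              digits, x$csf_naive_frac, digits, x$csf_diff_frac,
              digits, x$csf_mass))
  invisible(x)
}
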