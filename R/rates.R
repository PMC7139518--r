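.rate_names <- c("alpha1", "alpha2", "beta1", "beta2")
.cell_types <- c("CD4", "CD8", "B", "NK")

#' Transition rates for one lymphocyte lineage
#'
#' Container for the four per-step transition probabilities of the
#' four-stage blood/CSF trafficking model:
#'
#' * `alpha1` — migration of naive cells from peripheral blood (PB) into the
#'   cerebrospinal fluid (CSF);
#' * `alpha2` — migration of differentiated cells from PB into the CSF;
#' * `beta1` — differentiation of naive cells within the PB;
#' * `beta2` — differentiation of naive cells within the CSF.
#'
#' Rates are stored as fractions in \eqn{[0, 1]}; published tables usually
#' print them in percent (divide by 100 at the file boundary, see
#' [read_rates_csv()]).  Because the stationary probability of the PB-naive
#' stage is \eqn{x_1 = 1 - \alpha_1 - \beta_1}, the additional feasibility
#' constraint \eqn{\alpha_1 + \beta_1 \le 1} is enforced.
#'
#' @param alpha1,alpha2,beta1,beta2 Numeric scalars in `[0, 1]` (fractions,
#'   not percent).
#' @param cell_type Optional lineage label, one of `"CD4"`, `"CD8"`, `"B"`,
#'   `"NK"` (or `NA`).
#' @param group Optional clinical-group label (e.g. `"controls"`).
#' @return An object of class `"transition_rates"`: a list with the four
#'   rates and the two labels.
#' @examples
#' r <- transition_rates(0.0012, 0.0028, 0.106, 0.198, "CD8", "controls")
#' steady_state(r)
#' @seealso [validate_rates()], [reference_rates()], [steady_state()]
#' @export
transition_rates <- function(alpha1, alpha2, beta1, beta2,
                             cell_type = NA_character_,
                             group = NA_character_) {
  r <- structure(
    list(alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2),
         beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
         cell_type = as.character(cell_type), group = as.character(group)),
    class = "transition_rates")
  validate_rates(r)
}

#' Validate a set of transition rates
#'
#' Checks that all four rates are finite fractions in `[0, 1]` and that
#' `alpha1 + beta1 <= 1` (otherwise the PB-naive stage probability would be
#' negative).  Returns its input unchanged when valid.
#'
#' @param rates A [transition_rates()] object.
#' @return `rates`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending rate.
#' @export
validate_rates <- function(rates) {
  if (!inherits(rates, "transition_rates"))
    stop("`rates` must be a transition_rates object", call. = FALSE)
  for (nm in .rate_names) {
    v <- rates[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("rate `%s` must be a single finite number", nm),
           call. = FALSE)
    if (v < 0 || v > 1)
      stop(sprintf("rate `%s` = %g is outside [0, 1]; rates are fractions, not percent",
                   nm, v), call. = FALSE)
  }
  if (rates$alpha1 + rates$beta1 > 1)
    stop(sprintf("infeasible rates: alpha1 + beta1 = %g > 1 (PB-naive stage probability would be negative)",
                 rates$alpha1 + rates$beta1), call. = FALSE)
  rates
}

# numeric view in canonical order (alpha1, alpha2, beta1, beta2)
.rate_vec <- function(rates) {
  c(alpha1 = rates$alpha1, alpha2 = rates$alpha2,
    beta1 = rates$beta1, beta2 = rates$beta2)
}

#' @export
as.double.transition_rates <- function(x, ...) .rate_vec(x)

#' @export
print.transition_rates <- function(x, digits = 6, ...) {
  lab <- paste(stats::na.omit(c(x$cell_type, x$group)), collapse = " / ")
  cat("Transition rates", if (nzchar(lab)) paste0("(", lab, ")"), "\n")
  print(signif(.rate_vec(x), digits))
  invisible(x)
}

#' CSF-to-blood differentiation fold change
#'
#' Ratio `beta2 / beta1`: how much more (or less) likely a naive cell is to
#' differentiate within the CSF than within the peripheral blood.
#'
#' @param rates A [transition_rates()] object with `beta1 > 0`.
#' @return A positive number.
#' @examples
#' differentiation_fold(reference_rates("CD8", "controls")) # about 1.9
#' @export
differentiation_fold <- function(rates) {
  validate_rates(rates)
  if (rates$beta1 == 0)
    stop("beta1 is zero: fold change beta2/beta1 undefined", call. = FALSE)
  rates$beta2 / rates$beta1
}

#' Per-rate fold changes between two rate sets
#'
#' Elementwise ratios `a / b` for the four rates, used to quantify e.g.
#' treatment effects (a migration blocker lowers the alpha ratios, a
#' depleting therapy mostly moves the beta ratios).
#'
#' @param a,b [transition_rates()] objects; every rate of `b` must be
#'   strictly positive.
#' @return Named numeric vector of four fold changes
#'   (`alpha1`, `alpha2`, `beta1`, `beta2`).
#' @examples
#' rate_ratios(reference_rates("CD4", "RRMS_NAT"),
#'             reference_rates("CD4", "RRMS_naive"))
#' @export
rate_ratios <- function(a, b) {
  validate_rates(a); validate_rates(b)
  bv <- .rate_vec(b)
  if (any(bv == 0))
    stop(sprintf("zero denominator rate `%s` in `b`",
                 names(bv)[which(bv == 0)[1]]), call. = FALSE)
  .rate_vec(a) / bv
}
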