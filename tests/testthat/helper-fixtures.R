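# Shared fixtures: random feasible rate vectors and a dense linear-solve
# oracle, independent of the closed-form implementation.

random_valid_rates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a1 <- runif(n)
  b1 <- runif(n, 0, 1 - a1)
  cbind(alpha1 = a1, alpha2 = runif(n), beta1 = b1, beta2 = runif(n))
}

rates_from_row <- function(r) {
  transition_rates(r[["alpha1"]], r[["alpha2"]], r[["beta1"]], r[["beta2"]])
}

# brute-force stationary distribution: dense solve of the balance system
solve_stage_system <- function(rates) {
  sys <- stage_system(rates)
  as.numeric(solve(sys$matrix, sys$rhs))
}

cd8_controls <- function() reference_rates("CD8", "controls")
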