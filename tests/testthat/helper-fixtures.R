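# Shared fixtures: parameter sets from the study conditions and small
# numerical oracles used across test files.

mosaic <- mosaic_system()

params_at <- function(k = 10, nu = 1, ...) param_set(k = k, nu = nu, ...)

# central finite-difference Jacobian of a planar vector field
fd_jacobian <- function(fun, state, h = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    J[, j] <- (fun(state + e) - fun(state - e)) / (2 * h)
  }
  J
}

# seeded random interior states, away from the singular edge f = 1
random_interior_states <- function(n, seed = 42) {
  set.seed(seed)
  cbind(f = runif(n, 0.05, 0.9), x = runif(n, 0.05, 0.95))
}

# independent characterization of the criticality switch on the interior
# Hopf locus: with the trailing-index symmetry of the derivative tensors
# the cubic normal-form coefficient is proportional to
# k * S'''(k - b) + 3 * S''(k - b) for the logistic S, so its zero solves
# k (1 - 6S + 6S^2) + 3 (1 - 2S) = 0.  Used as an oracle for find_bautin.
bautin_condition <- function(k, b) {
  S <- stats::plogis(k - b)
  k * (1 - 6 * S + 6 * S^2) + 3 * (1 - 2 * S)
}
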