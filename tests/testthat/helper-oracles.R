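# Independent oracles used across the suite.

# Fixation probabilities by solving the absorbing-chain linear system
# rho_k = rho_{k+1} p_k^+ + rho_k (1 - p_k^+ - p_k^-) + rho_{k-1} p_k^-
# with rho_0 = 0, rho_N = 1 (dense solve; independent of the product-form
# path in fixation_exact()).
fixation_linear_oracle <- function(N, F1, F2) {
  A <- matrix(0, N + 1, N + 1)
  b <- numeric(N + 1)
  A[1, 1] <- 1
  A[N + 1, N + 1] <- 1
  b[N + 1] <- 1
  for (k in seq_len(N - 1)) {
    tot <- k * F1 + (N - k) * F2
    p_up <- k * F1 / tot * (N - k) / N
    p_down <- (N - k) * F2 / tot * k / N
    A[k + 1, k] <- p_down
    A[k + 1, k + 1] <- -(p_up + p_down)
    A[k + 1, k + 2] <- p_up
  }
  as.numeric(solve(A, b))
}

# Fitness of both species at the balanced environment from composite sums.
balanced_fitness <- function(w, S) 1 - w + w * S

# Standard figure-style configuration.
fig_params <- function(w = 0.1, a = 0, dt = 0.01, S1 = 1.75, S2 = 1.5, N = 100) {
  model_params(N = N, w = w, a = a, dt = dt, S1 = S1, S2 = S2)
}
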