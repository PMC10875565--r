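#' One-step transition probabilities of the Moran birth-death process
#'
#' In each step one individual is chosen to reproduce with probability
#' proportional to fitness and one is chosen uniformly to die. With `k`
#' copies of species 1,
#' `p_up = kF1/(kF1 + (N-k)F2) * (N-k)/N` and
#' `p_down = (N-k)F2/(kF1 + (N-k)F2) * k/N`; with the remaining
#' probability the composition is unchanged. Both vanish at the absorbing
#' states `k = 0` and `k = N`.
#'
#' @param k Count(s) of species-1 individuals, each in `0..N`; vectorised.
#' @param N Population size.
#' @param F1,F2 Positive fitnesses of species 1 and 2.
#' @return A tibble with columns `k`, `p_up`, `p_down`.
#' @examples
#' transition_probs(50, 100, 1, 1) # neutral midpoint: 0.25 / 0.25
#' @export
transition_probs <- function(k, N, F1, F2) {
  if (any(k != round(k)) || any(k < 0) || any(k > N)) {
    abort("`k` must be integer(s) in 0..N.", class = "ecomoran_domain_error")
  }
  if (F1 <= 0 || F2 <= 0) {
    abort("fitnesses must be positive.", class = "ecomoran_invalid_parameter")
  }
  tot <- k * F1 + (N - k) * F2
  tibble(
    k = as.integer(k),
    p_up = k * F1 / tot * (N - k) / N,
    p_down = (N - k) * F2 / tot * k / N
  )
}

#' Exact fixation probabilities without feedback
#'
#' For the feedback-free process (`a = 0`, balanced shares `y1 = y2 = 1/2`)
#' the fitness ratio `gamma = F2/F1` is constant in `k`, and the
#' absorbing-chain recurrence
#' `rho_k = rho_{k+1} p_k^+ + rho_k (1 - p_k^+ - p_k^-) + rho_{k-1} p_k^-`
#' with `rho_0 = 0`, `rho_N = 1` has the product-form solution
#' `rho_k = (1 + sum_{j=1}^{k-1} gamma^j) / (1 + sum_{j=1}^{N-1} gamma^j)`,
#' i.e. `(1 - gamma^k)/(1 - gamma^N)` away from neutrality and `k/N` at
#' `gamma = 1`.
#'
#' Evaluation is numerically stable: near neutrality
#' (`|gamma - 1| <= 1e-8`) the geometric sums are accumulated
#' incrementally; otherwise the closed form is evaluated through
#' `expm1()` on the log scale, avoiding overflow of `gamma^N`.
#'
#' @param N Population size.
#' @param F1,F2 Positive fitnesses of species 1 and 2 (constant in `k`).
#' @return An object of class `fixation_curve`; use [tidy()] for the
#'   `(k, rho)` table, [glance()] for a one-row summary, `$rho` for the
#'   raw length-`N+1` vector (`rho[k + 1]` is the probability that
#'   species 1 starting from `k` copies takes over).
#' @examples
#' fc <- fixation_exact(100, F1 = 1.075, F2 = 1.05)
#' glance(fc) # invasion rho_1 and competition rho_{N/2}
#' @export
fixation_exact <- function(N, F1, F2) {
  if (F1 <= 0 || F2 <= 0) {
    abort("fitnesses must be positive.", class = "ecomoran_invalid_parameter")
  }
  if (N < 2 || N != round(N)) {
    abort("`N` must be an integer >= 2.", class = "ecomoran_domain_error")
  }
  gamma <- F2 / F1
  k <- 0:N
  if (abs(gamma - 1) <= 1e-8) {
    # incremental accumulation of 1 + sum_{j=1}^{k-1} gamma^j
    s <- cumsum(c(0, cumprod(rep(gamma, N - 1))))
    rho <- c(0, (1 + s) / (1 + s[N]))
  } else {
    t <- log(gamma)
    rho <- if (t < 0) {
      expm1(k * t) / expm1(N * t)
    } else {
      exp((k - N) * t) * expm1(-k * t) / expm1(-N * t)
    }
  }
  structure(list(rho = rho, N = as.integer(N), F1 = F1, F2 = F2, gamma = gamma),
            class = "fixation_curve")
}

#' @export
print.fixation_curve <- function(x, ...) {
  cat(sprintf("<fixation_curve> N = %d, gamma = F2/F1 = %.6g\n  rho_1 = %.6g",
              x$N, x$gamma, x$rho[2]))
  if (x$N %% 2 == 0) cat(sprintf(", rho_{N/2} = %.6g", x$rho[x$N / 2 + 1]))
  cat("\n")
  invisible(x)
}

#' @rdname fixation_exact
#' @param x A `fixation_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fixation_curve <- function(x, ...) {
  tibble(k = 0:x$N, rho = x$rho)
}

#' @rdname fixation_exact
#' @exportS3Method generics::glance
glance.fixation_curve <- function(x, ...) {
  tibble(
    N = x$N, F1 = x$F1, F2 = x$F2, gamma = x$gamma,
    rho_invasion = x$rho[2],
    rho_competition = if (x$N %% 2 == 0) x$rho[x$N / 2 + 1] else NA_real_
  )
}

#' @rdname fixation_exact
#' @param object A `fixation_curve`.
#' @exportS3Method ggplot2::autoplot
autoplot.fixation_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$k, .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1 / object$N, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "initial count of species 1 (k)",
                  y = expression(rho[k]),
                  title = "Fixation probability vs initial count",
                  subtitle = "dashed: neutral k/N") +
    ggplot2::theme_minimal()
}

#' Weak-selection approximations of the fixation probability
#'
#' Under weak selection (`w << 1`) and balanced resource shares, expanding
#' the product-form solution to first order in `w` gives closed-form
#' approximations in terms of the composite sums `S_i = c_i/2 + d_i`:
#'
#' * invasion (`k0 = 1`):
#'   `rho_1 ~ (1/N) / (1 + w (N-1)/2 (S2 - S1))`
#' * competition (`k0 = N/2`):
#'   `rho_{N/2} ~ (1/2) (1 + w (N/2-1)/2 (S2 - S1)) / (1 + w (N-1)/2 (S2 - S1))`
#'
#' Both exceed their neutral baselines (`1/N`, `1/2`) exactly when
#' `S1 > S2`, the condition under which selection favors species 1.
#'
#' @param N Population size (even for the competition form).
#' @param w Selection intensity, `>= 0`.
#' @param S1,S2 Composite payoff sums of species 1 and 2.
#' @return The approximate fixation probability (scalar).
#' @examples
#' fixation_weak_invasion(100, 0.01, 1.75, 1.5)
#' fixation_weak_competition(100, 0.01, 1.75, 1.5)
#' @export
fixation_weak_invasion <- function(N, w, S1, S2) {
  if (w < 0) abort("`w` must be >= 0.", class = "ecomoran_invalid_parameter")
  den <- 1 + w * (N - 1) / 2 * (S2 - S1)
  if (den <= 0) {
    abort("weak-selection denominator is non-positive; the expansion is invalid here.",
          class = "ecomoran_approximation_error")
  }
  (1 / N) / den
}

#' @rdname fixation_weak_invasion
#' @export
fixation_weak_competition <- function(N, w, S1, S2) {
  if (N %% 2 != 0) {
    abort("competition scenario requires even `N`.", class = "ecomoran_domain_error")
  }
  if (w < 0) abort("`w` must be >= 0.", class = "ecomoran_invalid_parameter")
  num <- 1 + w * (N / 2 - 1) / 2 * (S2 - S1)
  den <- 1 + w * (N - 1) / 2 * (S2 - S1)
  if (num <= 0 || den <= 0) {
    abort("weak-selection denominator is non-positive; the expansion is invalid here.",
          class = "ecomoran_approximation_error")
  }
  0.5 * num / den
}

#' Which species does natural selection favor?
#'
#' Without feedback the favored species is decided by the composite sums
#' alone: species 1 iff `S1 > S2`. Equality is tested exactly; round
#' beforehand if a tolerance is wanted.
#'
#' @param S1,S2 Composite payoff sums.
#' @return One of `"favors_species_1"`, `"neutral"`, `"favors_species_2"`.
#' @examples
#' selection_preference(1.75, 1.5)
#' @export
selection_preference <- function(S1, S2) {
  if (S1 > S2) "favors_species_1"
  else if (S1 == S2) "neutral"
  else "favors_species_2"
}
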