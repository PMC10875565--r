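#' One Euler step of the resource-share dynamics
#'
#' The share of resource 1 follows
#' `dy1/dt = a y1 (1 - y1) (X1 - X2)` with `X1 = k`, `X2 = N - k`, the
#' symmetric reduction of the general dynamics in which both resources
#' respond identically to the presence of their paired species. One Euler
#' step of size `dt` gives
#' `y1 <- y1 + a y1 (1 - y1) (2k - N) dt`, clamped to \[0, 1\] as a
#' numerical guard (for `|a| N dt <= 1` the clamp is never active).
#' The share of resource 2 is `1 - y1` by complementarity.
#'
#' @param y1 Current share of resource 1, in \[0, 1\]; vectorised.
#' @param k Count of species-1 individuals, in `0..N`; vectorised.
#' @param N Population size.
#' @param a Feedback intensity (sign = feedback type).
#' @param dt Euler time step.
#' @return Updated share(s) of resource 1.
#' @examples
#' resource_step(0.5, k = 60, N = 100, a = 1, dt = 0.01) # 0.55
#' @export
resource_step <- function(y1, k, N, a, dt) {
  if (any(y1 < 0 | y1 > 1)) {
    abort("`y1` must lie in [0, 1].", class = "ecomoran_domain_error")
  }
  if (any(k < 0 | k > N)) {
    abort("`k` must lie in 0..N.", class = "ecomoran_domain_error")
  }
  pmin(pmax(y1 + a * y1 * (1 - y1) * (2 * k - N) * dt, 0), 1)
}

#' @rdname resource_step
#' @description
#' `resource_step_general()` steps the unreduced dynamics
#' `dy1/dt = y1 (1 - y1) (a1 X1 + b1 - a2 X2 - b2)`, in which each
#' resource has its own response `a_i` to its paired species and its own
#' baseline growth rate `b_i`. It reduces exactly to `resource_step()`
#' when `a1 = a2` and `b1 = b2`.
#' @param a1,b1 Response and baseline growth rate of resource 1.
#' @param a2,b2 Response and baseline growth rate of resource 2.
#' @export
resource_step_general <- function(y1, k, N, a1, b1, a2, b2, dt) {
  if (any(y1 < 0 | y1 > 1)) {
    abort("`y1` must lie in [0, 1].", class = "ecomoran_domain_error")
  }
  if (any(k < 0 | k > N)) {
    abort("`k` must lie in 0..N.", class = "ecomoran_domain_error")
  }
  drift <- a1 * k + b1 - a2 * (N - k) - b2
  pmin(pmax(y1 + y1 * (1 - y1) * drift * dt, 0), 1)
}

#' Advance the coupled system by one time step
#'
#' One time step is: (1) a birth-death event — with probabilities
#' `p_up` / `p_down` computed from the fitnesses at the *entry* resource
#' share, `k` increments, decrements, or stays; then (2) one Euler
#' resource step using the *post-update* count. Species change first,
#' environment second. Uses R's global RNG (`set.seed()` for
#' reproducibility).
#'
#' @param state A [system_state()]; must not be absorbed (`0 < k < N`).
#' @param params A [model_params()].
#' @return The updated `system_state` (step index incremented).
#' @export
moran_step <- function(state, params) {
  k <- state$k
  N <- params$N
  if (k <= 0L || k >= N) {
    abort("cannot step an absorbed state (k = 0 or k = N).",
          class = "ecomoran_logic_error")
  }
  Fs <- fitness_pair(params, state$y1)
  tot <- k * Fs[1] + (N - k) * Fs[2]
  p_up <- k * Fs[1] / tot * (N - k) / N
  p_down <- (N - k) * Fs[2] / tot * k / N
  u <- runif(1)
  k_new <- if (u < p_up) k + 1L else if (u < p_up + p_down) k - 1L else k
  y_new <- resource_step(state$y1, k_new, N, params$a, params$dt)
  system_state(k_new, y_new, N, state$step + 1L)
}

#' Run one replicate to fixation
#'
#' Iterates [moran_step()] until one species takes over (`k = 0` or
#' `k = N`). Uses R's global RNG. A replicate that fails to absorb within
#' `max_steps` raises an error of class `ecomoran_non_absorption`
#' carrying the partial state — it is never silently truncated, which
#' would bias downstream estimates.
#'
#' @param params A [model_params()].
#' @param k0 Initial count of species 1 (`0..N`; 1 = invasion,
#'   `N/2` = competition).
#' @param y0 Initial share of resource 1 (default 1/2: resources start
#'   balanced).
#' @param max_steps Step cap; absorption takes `O(N^2)` steps in typical
#'   regimes, so the default only catches pathological parameters.
#' @return An object of class `replicate_outcome`: list with `winner`
#'   (1 or 2), `steps` to absorption, and `final_y1`.
#' @examples
#' set.seed(1)
#' p <- model_params(N = 20, w = 0.1, a = 0, dt = 0.01, S1 = 1.75, S2 = 1.5)
#' simulate_to_fixation(p, k0 = 10)
#' @export
simulate_to_fixation <- function(params, k0, y0 = 0.5, max_steps = 1e7) {
  if (max_steps < 1) abort("`max_steps` must be >= 1.", class = "ecomoran_domain_error")
  state <- system_state(k0, y0, params$N)
  while (state$k > 0L && state$k < params$N) {
    if (state$step >= max_steps) {
      abort(sprintf("no absorption within %g steps (k = %d, y1 = %g).",
                    max_steps, state$k, state$y1),
            class = "ecomoran_non_absorption", state = state)
    }
    state <- moran_step(state, params)
  }
  structure(list(winner = if (state$k == params$N) 1L else 2L,
                 steps = state$step, final_y1 = state$y1),
            class = "replicate_outcome")
}

#' @export
print.replicate_outcome <- function(x, ...) {
  cat(sprintf("<replicate_outcome> winner = species %d after %d steps (final y1 = %.4g)\n",
              x$winner, x$steps, x$final_y1))
  invisible(x)
}

#' Monte-Carlo estimate of a fixation probability
#'
#' Runs `n_reps` independent replicates of the coupled process from
#' `k0` copies of species 1 and balanced resources, and estimates the
#' probability that species 1 takes over, with its binomial standard
#' error `sqrt(p(1-p)/n)`. Replicates run in compiled code; replicate
#' `r`'s RNG stream depends only on `(seed, r)`, so results are exactly
#' reproducible and extending `n_reps` never reshuffles earlier
#' replicates.
#'
#' @inheritParams simulate_to_fixation
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return An object of class `fixation_estimate`; [glance()] gives the
#'   one-row summary, [tidy()] the per-replicate outcome table.
#' @examples
#' p <- model_params(N = 50, w = 0.1, a = 0, dt = 0.01, S1 = 1.75, S2 = 1.5)
#' glance(estimate_fixation(p, k0 = 25, n_reps = 500, seed = 7))
#' @export
estimate_fixation <- function(params, k0, n_reps = 10000, seed,
                              y0 = 0.5, max_steps = 1e7) {
  stopifnot(inherits(params, "model_params"))
  if (n_reps < 1) abort("`n_reps` must be >= 1.", class = "ecomoran_domain_error")
  if (k0 < 0 || k0 > params$N || k0 != round(k0)) {
    abort("`k0` must be an integer in 0..N.", class = "ecomoran_domain_error")
  }
  p <- params$payoffs
  res <- cpp_simulate_batch(params$N, params$w, params$a,
                            p$c1, p$d1, p$c2, p$d2, params$dt,
                            as.integer(k0), y0,
                            as.integer(n_reps), as.integer(seed), max_steps)
  if (anyNA(res$winner)) {
    idx <- which(is.na(res$winner))[1]
    abort(sprintf("replicate %d did not absorb within %g steps.", idx, max_steps),
          class = "ecomoran_non_absorption", replicate = idx)
  }
  p_hat <- mean(res$winner == 1L)
  structure(list(
    p_hat = p_hat,
    se = sqrt(p_hat * (1 - p_hat) / n_reps),
    n_reps = as.integer(n_reps),
    seed = as.integer(seed),
    k0 = as.integer(k0),
    params = params,
    outcomes = tibble(replicate = seq_len(n_reps),
                      winner = res$winner,
                      steps = res$steps,
                      final_y1 = res$final_y1)
  ), class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("<fixation_estimate> p_hat = %.4f (SE %.4f), k0 = %d, n = %d, seed = %d\n",
              x$p_hat, x$se, x$k0, x$n_reps, x$seed))
  invisible(x)
}

#' @rdname estimate_fixation
#' @param x,object A `fixation_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fixation_estimate <- function(x, ...) {
  x$outcomes
}

#' @rdname estimate_fixation
#' @exportS3Method generics::glance
glance.fixation_estimate <- function(x, ...) {
  tibble(p_hat = x$p_hat, se = x$se, n_reps = x$n_reps, k0 = x$k0,
         seed = x$seed, N = x$params$N, w = x$params$w, a = x$params$a,
         dt = x$params$dt,
         S1 = composites(x$params)[1], S2 = composites(x$params)[2],
         mean_steps = mean(x$outcomes$steps))
}

#' Early-stage fitness dominance of species 1
#'
#' Tracks, over the first `horizon` time steps, the fraction of
#' replicates in which species 1's payoff strictly exceeds species 2's
#' (`f1 > f2`; ties count as "not higher"). Without feedback the shares
#' never move, so an initially inferior species never gains the fitness
#' lead; with feedback, demographic luck early on can move the
#' environment in a species' favor. Replicates that absorb before the
#' horizon keep contributing: their environment continues to evolve
#' under the fixed counts (`X1 - X2 = +N` or `-N`).
#'
#' @inheritParams estimate_fixation
#' @param horizon Number of time steps to record (default 500).
#' @return An object of class `early_stage_series`; [tidy()] gives the
#'   `(step, proportion)` table.
#' @examples
#' p <- model_params(N = 50, w = 0.1, a = 1, dt = 0.01, S1 = 1.25, S2 = 1.5)
#' es <- early_stage_fitness_proportion(p, k0 = 25, horizon = 100,
#'                                      n_reps = 200, seed = 3)
#' tail(tidy(es))
#' @export
early_stage_fitness_proportion <- function(params, k0, horizon = 500,
                                           n_reps = 10000, seed, y0 = 0.5) {
  stopifnot(inherits(params, "model_params"))
  if (horizon < 1) abort("`horizon` must be >= 1.", class = "ecomoran_domain_error")
  if (n_reps < 1) abort("`n_reps` must be >= 1.", class = "ecomoran_domain_error")
  if (k0 < 0 || k0 > params$N || k0 != round(k0)) {
    abort("`k0` must be an integer in 0..N.", class = "ecomoran_domain_error")
  }
  p <- params$payoffs
  prop <- cpp_early_stage(params$N, params$w, params$a,
                          p$c1, p$d1, p$c2, p$d2, params$dt,
                          as.integer(k0), y0,
                          as.integer(horizon), as.integer(n_reps),
                          as.integer(seed))
  structure(list(proportion_f1_higher = prop,
                 horizon = as.integer(horizon),
                 n_reps = as.integer(n_reps),
                 seed = as.integer(seed),
                 k0 = as.integer(k0),
                 params = params),
            class = "early_stage_series")
}

#' @export
print.early_stage_series <- function(x, ...) {
  cat(sprintf("<early_stage_series> horizon = %d, n = %d; proportion at final step = %.4f\n",
              x$horizon, x$n_reps,
              x$proportion_f1_higher[x$horizon]))
  invisible(x)
}

#' @rdname early_stage_fitness_proportion
#' @param x,object An `early_stage_series`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.early_stage_series <- function(x, ...) {
  tibble(step = seq_len(x$horizon), proportion = x$proportion_f1_higher)
}

#' @rdname early_stage_fitness_proportion
#' @exportS3Method generics::glance
glance.early_stage_series <- function(x, ...) {
  tibble(horizon = x$horizon, n_reps = x$n_reps, seed = x$seed, k0 = x$k0,
         a = x$params$a, w = x$params$w, dt = x$params$dt,
         S1 = composites(x$params)[1], S2 = composites(x$params)[2],
         proportion_final = x$proportion_f1_higher[x$horizon])
}

#' @rdname early_stage_fitness_proportion
#' @exportS3Method ggplot2::autoplot
autoplot.early_stage_series <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$step, .data$proportion)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time step",
                  y = "proportion of replicates with f1 > f2",
                  title = "Early-stage fitness dominance of species 1") +
    ggplot2::theme_minimal()
}
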