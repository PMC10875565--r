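#' Specify a fixation-probability parameter sweep
#'
#' A sweep runs one Monte-Carlo fixation estimate per point of the grid
#' `a x w x S1` (feedback intensity, selection intensity, composite sum
#' of species 1), holding `S2`, `N` and `dt` fixed. The scenario fixes
#' the initial count: `"invasion"` starts from a single individual
#' (`k0 = 1`), `"competition"` from half the population (`k0 = N/2`,
#' even `N` required).
#'
#' @param a Vector of feedback intensities (outer loop of the grid).
#' @param w Vector of selection intensities.
#' @param S1 Vector of composite sums for species 1.
#' @param S2 Composite sum of species 2 (fixed; default 1.5).
#' @param N Population size (default 100).
#' @param dt Euler time step (default 0.01).
#' @param scenario `"invasion"` or `"competition"`.
#' @param n_reps Replicates per grid point (default 10000; use 2000 for
#'   a fast pass).
#' @param seed Integer root seed; grid point `i` (in iteration order,
#'   `a` outer, then `w`, then `S1`) uses `seed + i - 1`.
#' @return An object of class `sweep_spec`.
#' @examples
#' sweep_spec(a = c(0, 0.5, 1), w = 0.1, S1 = 1.75, n_reps = 2000, seed = 1)
#' @export
sweep_spec <- function(a, w, S1, S2 = 1.5, N = 100, dt = 0.01,
                       scenario = c("invasion", "competition"),
                       n_reps = 10000, seed) {
  scenario <- match.arg(scenario)
  if (length(a) < 1 || length(w) < 1 || length(S1) < 1) {
    abort("grids over `a`, `w` and `S1` must be non-empty.",
          class = "ecomoran_invalid_parameter")
  }
  if (scenario == "competition" && N %% 2 != 0) {
    abort("competition scenario requires even `N`.", class = "ecomoran_domain_error")
  }
  structure(list(a = a, w = w, S1 = S1, S2 = S2, N = as.integer(N), dt = dt,
                 scenario = scenario, n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("<sweep_spec> %s scenario: %d a-points x %d w x %d S1 (S2 = %g, N = %d, dt = %g, %d reps, seed %d)\n",
              x$scenario, length(x$a), length(x$w), length(x$S1),
              x$S2, x$N, x$dt, x$n_reps, x$seed))
  invisible(x)
}

#' Degree-of-preference metric
#'
#' The excess of a fixation probability over its neutral baseline:
#' `p - 1/N` in the invasion scenario (a neutral invader fixes with
#' probability `1/N`) and `p - 1/2` in the competition scenario. Positive
#' values mean the realized dynamics favor species 1.
#'
#' @param p_hat Fixation probability (estimate or exact); vectorised.
#' @param scenario `"invasion"` or `"competition"`.
#' @param N Population size (used for the invasion baseline).
#' @return The signed preference value(s).
#' @examples
#' preference_metric(0.764, "competition", 100) # 0.264
#' @export
preference_metric <- function(p_hat, scenario = c("invasion", "competition"), N) {
  scenario <- match.arg(scenario)
  if (scenario == "invasion") p_hat - 1 / N else p_hat - 0.5
}

#' Run a fixation-probability sweep
#'
#' Executes one [estimate_fixation()] per grid point of a [sweep_spec()],
#' in grid iteration order (`a` outer, then `w`, then `S1`). The result
#' is one tibble row per point with the estimate, its binomial standard
#' error, and the degree-of-preference metric. A grid point whose
#' parameters fail validation becomes an error row (`status` holds the
#' reason, estimates are `NA`) and the sweep continues. Deterministic
#' given the spec's seed.
#'
#' @param spec A [sweep_spec()].
#' @return A tibble of class `sweep_result` with columns `scenario, a, w,
#'   S1, S2, N, dt, k0, n_reps, seed, p_hat, se, preference, status`.
#' @examples
#' run_sweep(sweep_spec(a = 0, w = 0.1, S1 = 1.5, N = 20, n_reps = 200, seed = 1))
#' @export
run_sweep <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  k0 <- if (spec$scenario == "invasion") 1L else spec$N %/% 2L
  grid <- tidyr::expand_grid(a = spec$a, w = spec$w, S1 = spec$S1)
  rows <- purrr::imap(purrr::transpose(grid), function(pt, i) {
    point_seed <- spec$seed + i - 1L
    est <- tryCatch({
      params <- model_params(N = spec$N, w = pt$w, a = pt$a, dt = spec$dt,
                             S1 = pt$S1, S2 = spec$S2)
      glance(estimate_fixation(params, k0 = k0, n_reps = spec$n_reps,
                               seed = point_seed))
    }, error = function(e) conditionMessage(e))
    if (is.character(est)) {
      tibble(scenario = spec$scenario, a = pt$a, w = pt$w, S1 = pt$S1,
             S2 = spec$S2, N = spec$N, dt = spec$dt, k0 = k0,
             n_reps = spec$n_reps, seed = point_seed,
             p_hat = NA_real_, se = NA_real_, preference = NA_real_,
             status = est)
    } else {
      tibble(scenario = spec$scenario, a = pt$a, w = pt$w, S1 = pt$S1,
             S2 = spec$S2, N = spec$N, dt = spec$dt, k0 = k0,
             n_reps = spec$n_reps, seed = point_seed,
             p_hat = est$p_hat, se = est$se,
             preference = preference_metric(est$p_hat, spec$scenario, spec$N),
             status = "ok")
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' @rdname run_sweep
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_result <- function(object, ...) {
  dat <- dplyr::filter(object, .data$status == "ok")
  ggplot2::ggplot(dat, ggplot2::aes(.data$a, .data$preference,
                                    colour = factor(.data$S1))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$preference - .data$se,
                                          ymax = .data$preference + .data$se)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~w, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "feedback intensity a",
                  y = "degree of selection preference",
                  colour = "S1",
                  title = sprintf("%s scenario", dat$scenario[1])) +
    ggplot2::theme_minimal()
}

#' Run an early-stage fitness-dominance experiment
#'
#' For every point of the grid `a x w x S1` (competition scenario,
#' `k0 = N/2` by default), records the per-step proportion of replicates
#' in which species 1 holds the strict fitness lead over the first
#' `horizon` steps. Returns one row per grid point with the final-step
#' proportion and the full series nested in a list column; use
#' `tidyr::unnest(res, series)` for a long, TSV-ready table.
#'
#' @inheritParams sweep_spec
#' @param horizon Number of time steps to record (default 500).
#' @param k0 Initial count of species 1 (default `N/2`).
#' @return A tibble of class `early_stage_result`, one row per grid
#'   point, with columns `a, w, S1, S2, N, dt, k0, horizon, n_reps,
#'   seed, proportion_final, status` and list column `series`.
#' @examples
#' res <- run_early_stage_experiment(a = c(0, 1), w = 0.1, S1 = 1.25,
#'                                   N = 20, horizon = 50, n_reps = 200, seed = 1)
#' res$proportion_final
#' @export
run_early_stage_experiment <- function(a, w, S1, S2 = 1.5, N = 100, dt = 0.01,
                                       horizon = 500, k0 = N %/% 2,
                                       n_reps = 10000, seed) {
  grid <- tidyr::expand_grid(a = a, w = w, S1 = S1)
  rows <- purrr::imap(purrr::transpose(grid), function(pt, i) {
    point_seed <- as.integer(seed) + i - 1L
    res <- tryCatch({
      params <- model_params(N = N, w = pt$w, a = pt$a, dt = dt,
                             S1 = pt$S1, S2 = S2)
      early_stage_fitness_proportion(params, k0 = k0, horizon = horizon,
                                     n_reps = n_reps, seed = point_seed)
    }, error = function(e) conditionMessage(e))
    base <- tibble(a = pt$a, w = pt$w, S1 = pt$S1, S2 = S2, N = N, dt = dt,
                   k0 = k0, horizon = horizon, n_reps = n_reps,
                   seed = point_seed)
    if (is.character(res)) {
      dplyr::mutate(base, proportion_final = NA_real_, status = res,
                    series = list(tibble(step = integer(), proportion = double())))
    } else {
      dplyr::mutate(base,
                    proportion_final = res$proportion_f1_higher[horizon],
                    status = "ok", series = list(tidy(res)))
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("early_stage_result", class(out))
  out
}

#' @rdname run_early_stage_experiment
#' @param object An `early_stage_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.early_stage_result <- function(object, ...) {
  dat <- tidyr::unnest(dplyr::filter(object, .data$status == "ok"), "series")
  ggplot2::ggplot(dat, ggplot2::aes(.data$step, .data$proportion,
                                    colour = factor(.data$a))) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(S1 ~ w, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time step",
                  y = "proportion of replicates with f1 > f2",
                  colour = "a",
                  title = "Early-stage fitness dominance of species 1") +
    ggplot2::theme_minimal()
}
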