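#' Payoff parameters for the two species
#'
#' Each species draws its payoff from the resource it is paired with:
#' `f_i = c_i * y_i + d_i`, where `y_i` is the share of resource i
#' (`y2 = 1 - y1`), `c_i` is the payoff slope in the resource share and
#' `d_i` a baseline payoff. Both must be non-negative so that payoffs,
#' and hence birth weights, stay non-negative on `y` in \[0, 1\].
#'
#' Figures in this model family are usually indexed by the composite sum
#' `S_i = c_i/2 + d_i`, the payoff at the balanced environment `y = 1/2`;
#' see [composite_sum()] and [decompose_composite()].
#'
#' @param c1,d1 Slope and baseline payoff of species 1.
#' @param c2,d2 Slope and baseline payoff of species 2.
#' @return An object of class `payoff_params`.
#' @examples
#' payoff_params(c1 = 0.5, d1 = 1.5, c2 = 0.5, d2 = 1.25)
#' @export
payoff_params <- function(c1, d1, c2, d2) {
  for (nm in c("c1", "d1", "c2", "d2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm),
            class = "ecomoran_invalid_parameter")
    }
    if (v < 0) {
      abort(sprintf("`%s` must be non-negative (payoffs must stay >= 0 on y in [0,1]).", nm),
            class = "ecomoran_invalid_parameter")
    }
  }
  structure(list(c1 = c1, d1 = d1, c2 = c2, d2 = d2),
            class = "payoff_params")
}

#' Full model parameter bundle
#'
#' Bundles everything one configuration of the coupled species-environment
#' model needs: population size `N`, selection intensity `w`, feedback
#' intensity `a`, the payoff parameters, and the Euler time step `dt` for
#' the resource-share update. Payoffs may be given either raw
#' (`c1, d1, c2, d2`) or as composite sums (`S1, S2`, the payoff at the
#' balanced environment), in which case the convention `c = 0.5`,
#' `d = S - 0.25` is used. Raw values take precedence when both are given.
#'
#' `a > 0` is positive feedback (abundance improves a species' own
#' resource share), `a < 0` negative feedback, `a = 0` none. Values of
#' `a` outside \[-1, 1\] are accepted but flagged with a warning, since
#' the model is normally studied inside that range.
#'
#' @param N Population size (integer, at least 2); fixed over time.
#' @param w Selection intensity in \[0, 1\]; fitness is `F = 1 - w + w f`.
#'   `w = 0` is pure drift.
#' @param a Feedback intensity; sign gives the feedback type.
#' @param dt Euler time step of the resource update, in model time units;
#'   one birth-death event happens per `dt`, so `dt` sets the
#'   species/environment timescale ratio.
#' @param c1,d1,c2,d2 Raw payoff parameters (see [payoff_params()]).
#' @param S1,S2 Composite payoff sums `c/2 + d`; used when raw values are
#'   not supplied.
#' @param payoffs Optionally, a ready-made [payoff_params()] object.
#' @return An object of class `model_params`.
#' @examples
#' # Fig.-style configuration: dominant species 1
#' model_params(N = 100, w = 0.1, a = 0, dt = 0.01, S1 = 1.75, S2 = 1.5)
#' @export
model_params <- function(N, w, a, dt,
                         c1 = NULL, d1 = NULL, c2 = NULL, d2 = NULL,
                         S1 = NULL, S2 = NULL, payoffs = NULL) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 2 || N != round(N)) {
    abort("`N` must be a single integer >= 2.", class = "ecomoran_invalid_parameter")
  }
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0 || w > 1) {
    abort("`w` must be a single number in [0, 1].", class = "ecomoran_invalid_parameter")
  }
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a)) {
    abort("`a` must be a single finite number.", class = "ecomoran_invalid_parameter")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number.", class = "ecomoran_invalid_parameter")
  }
  if (abs(a) > 1) {
    warn(sprintf("feedback intensity a = %g lies outside the usual [-1, 1] range.", a),
         class = "ecomoran_flagged_parameter")
  }

  if (is.null(payoffs)) {
    raw <- list(c1 = c1, d1 = d1, c2 = c2, d2 = d2)
    if (all(!vapply(raw, is.null, logical(1)))) {
      payoffs <- payoff_params(c1, d1, c2, d2)
    } else if (!is.null(S1) && !is.null(S2)) {
      p1 <- decompose_composite(S1)
      p2 <- decompose_composite(S2)
      payoffs <- payoff_params(p1[["c"]], p1[["d"]], p2[["c"]], p2[["d"]])
    } else {
      abort("supply either all of `c1, d1, c2, d2` or both `S1, S2` (or `payoffs`).",
            class = "ecomoran_invalid_parameter")
    }
  } else if (!inherits(payoffs, "payoff_params")) {
    abort("`payoffs` must be a `payoff_params` object.",
          class = "ecomoran_invalid_parameter")
  }

  # eager validation: fitness must be positive at both environment extremes
  for (f in c(payoffs$d1, payoffs$c1 + payoffs$d1, payoffs$d2, payoffs$c2 + payoffs$d2)) {
    fitness(f, w)
  }

  structure(list(N = as.integer(N), w = w, a = a, dt = dt, payoffs = payoffs),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  p <- x$payoffs
  cat(sprintf(
    "<model_params> N = %d, w = %g, a = %g, dt = %g\n  species 1: f = %g y + %g  (S1 = %g)\n  species 2: f = %g y + %g  (S2 = %g)\n",
    x$N, x$w, x$a, x$dt,
    p$c1, p$d1, composite_sum(p$c1, p$d1),
    p$c2, p$d2, composite_sum(p$c2, p$d2)))
  invisible(x)
}

#' Instantaneous system state
#'
#' Records the count `k` of species-1 individuals (species 2 has `N - k`),
#' the share `y1` of resource 1 (`y2 = 1 - y1`), and the step index.
#' `k = 0` and `k = N` are absorbing for the species component.
#'
#' @param k Count of species-1 individuals, in `0..N`.
#' @param y1 Share of resource 1, in \[0, 1\].
#' @param N Population size (for validation of `k`).
#' @param step Non-negative time-step index.
#' @return An object of class `system_state`.
#' @export
system_state <- function(k, y1, N, step = 0L) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 0 || k > N) {
    abort("`k` must be an integer in 0..N.", class = "ecomoran_domain_error")
  }
  if (!is.numeric(y1) || length(y1) != 1L || y1 < 0 || y1 > 1) {
    abort("`y1` must lie in [0, 1].", class = "ecomoran_domain_error")
  }
  if (step < 0 || step != round(step)) {
    abort("`step` must be a non-negative integer.", class = "ecomoran_domain_error")
  }
  structure(list(k = as.integer(k), y1 = y1, N = as.integer(N),
                 step = as.integer(step)),
            class = "system_state")
}

#' Payoff of a species given its resource share
#'
#' `f = c * y + d`: linear in the share `y` of the species' own resource.
#'
#' @param y Resource share in \[0, 1\]; vectorised.
#' @param c Payoff slope.
#' @param d Baseline payoff.
#' @return Payoff value(s) `c * y + d`.
#' @examples
#' payoff(0.5, c = 0.5, d = 1.25) # composite sum 1.5
#' @export
payoff <- function(y, c, d) {
  if (any(!is.finite(y)) || any(y < 0 | y > 1)) {
    abort("`y` must lie in [0, 1].", class = "ecomoran_domain_error")
  }
  c * y + d
}

#' Fitness under selection intensity w
#'
#' `F = 1 - w + w * f`: a convex combination of the neutral baseline 1 and
#' the payoff `f`. At `w = 0` fitness is 1 for everyone (pure drift); at
#' `w = 1` fitness equals the payoff. `w << 1` is weak selection.
#'
#' @param f Payoff value(s), non-negative.
#' @param w Selection intensity in \[0, 1\].
#' @return Fitness value(s); errors if any would be non-positive, since
#'   fitnesses act as birth-lottery weights.
#' @examples
#' fitness(1.5, w = 0.1) # 1.05
#' @export
fitness <- function(f, w) {
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1) {
    abort("`w` must be a single number in [0, 1].", class = "ecomoran_invalid_parameter")
  }
  if (any(f < 0)) {
    abort("payoffs must be non-negative.", class = "ecomoran_invalid_parameter")
  }
  F <- 1 - w + w * f
  if (any(F <= 0)) {
    abort("resulting fitness is non-positive; birth weights must be > 0.",
          class = "ecomoran_invalid_parameter")
  }
  F
}

#' Composite payoff sum and its inverse
#'
#' `composite_sum(c, d) = c/2 + d` is the payoff at the balanced
#' environment `y = 1/2`, the quantity that decides which species natural
#' selection favors in the absence of feedback. `decompose_composite()`
#' inverts it under a fixed slope (default 0.5), so figure-style
#' configurations indexed by `S` map back to raw `(c, d)`.
#'
#' @param c Payoff slope.
#' @param d Baseline payoff.
#' @return `composite_sum()`: the scalar `c/2 + d`.
#' @examples
#' composite_sum(0.5, 1.25) # 1.5
#' decompose_composite(1.75) # c = 0.5, d = 1.5
#' @export
composite_sum <- function(c, d) {
  c / 2 + d
}

#' @rdname composite_sum
#' @param S Composite sum to invert.
#' @param c_fixed Slope to hold fixed in the decomposition.
#' @return `decompose_composite()`: a named vector `c(c = , d = )` with
#'   `d = S - c_fixed/2`; errors if the implied `d` is negative.
#' @export
decompose_composite <- function(S, c_fixed = 0.5) {
  d <- S - c_fixed / 2
  if (d < 0) {
    abort(sprintf("composite sum %g implies a negative baseline d under slope c = %g.",
                  S, c_fixed),
          class = "ecomoran_invalid_parameter")
  }
  c(c = c_fixed, d = d)
}

# composite sums of a model_params object, species order (S1, S2)
composites <- function(params) {
  p <- params$payoffs
  c(composite_sum(p$c1, p$d1), composite_sum(p$c2, p$d2))
}

# fitnesses of both species at resource share y1, species order (F1, F2)
fitness_pair <- function(params, y1) {
  p <- params$payoffs
  c(fitness(payoff(y1, p$c1, p$d1), params$w),
    fitness(payoff(1 - y1, p$c2, p$d2), params$w))
}
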