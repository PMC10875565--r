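---
title: "Eco-evolutionary Moran dynamics with environmental feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eco-evolutionary Moran dynamics with environmental feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecomoran)
library(dplyr)
```

## The model

`ecomoran` studies a fixed-size population of `N` individuals split between
two species (equally: two genotypes, phenotypes, or strategies), each paired
with its own resource. The state is the pair `(k, y1)`: the count of
species-1 individuals and the share of resource 1 in the total resource
pool (`y2 = 1 - y1`).

**Species dynamics.** Each time step is one Moran birth–death event: one
individual reproduces, chosen with probability proportional to fitness, and
one dies, chosen uniformly. A species' payoff is linear in its own resource
share, `f_i = c_i y_i + d_i`, and fitness blends that payoff with a neutral
baseline, `F_i = 1 - w + w f_i`, where the selection intensity `w` in
`[0, 1]` controls how much payoff differences matter (`w = 0` is pure
drift). The step-up/step-down probabilities are

```
p_k^+ = [k F1 / (k F1 + (N-k) F2)] * (N-k)/N
p_k^- = [(N-k) F2 / (k F1 + (N-k) F2)] * k/N
```

with `k = 0` and `k = N` absorbing.

**Environment dynamics.** Each resource grows at a rate that depends on the
abundance of its paired species. After reducing absolute amounts to shares,
the share of resource 1 obeys

```
dy1/dt = a * y1 * (1 - y1) * (X1 - X2),      X1 = k, X2 = N - k,
```

and `y2` obeys the same equation with the sign flipped. The single
parameter `a` carries the feedback: `a > 0` means an abundant species
improves its own resource share (positive feedback), `a < 0` means
abundance erodes it (negative feedback), `a = 0` decouples species and
environment. The simulator advances this equation by one Euler step of
size `dt` per birth–death event, so `dt` *is* the timescale ratio between
demography and environment.

**Update ordering.** Within one time step the species moves first and the
environment second: the birth–death lottery uses the fitnesses at the
entry value of `y1`, and the Euler step then uses the post-update counts.
This ordering is part of the model definition, not an implementation
convenience; the alternative (environment first) would give the invading
species one extra step of environmental influence.

Two scenarios recur throughout. *Invasion* starts from a single species-1
individual (`k0 = 1`); the neutral reference fixation probability is
`1/N`. *Competition* starts from `k0 = N/2`; the neutral reference is
`1/2`. The excess over the reference — `preference_metric()` — measures
how strongly the realized dynamics favor species 1.

## The feedback-free baseline, exactly

With `a = 0` and balanced shares (`y1 = y2 = 1/2`), the fitness ratio
`gamma = F2/F1` is constant in `k` and the fixation probabilities solve the
absorbing tridiagonal recurrence exactly:

```{r exact}
F1 <- fitness(payoff(0.5, 0.5, 1.5), w = 0.1)   # S1 = 1.75
F2 <- fitness(payoff(0.5, 0.5, 1.25), w = 0.1)  # S2 = 1.5
fc <- fixation_exact(100, F1, F2)
glance(fc)
```

Only the *composite sum* `S_i = c_i/2 + d_i` — the payoff at the balanced
environment — enters this baseline, which is why the package accepts
configurations parameterised by `(S1, S2)` directly. Selection favors
species 1 exactly when `S1 > S2` (`selection_preference()`), and both the
invasion and competition probabilities then exceed their neutral
references.

For weak selection, `fixation_weak_invasion()` and
`fixation_weak_competition()` give the first-order closed forms

```
rho_1    ≈ (1/N) / (1 + w (N-1)/2 (S2 - S1))
rho_N/2  ≈ (1/2) (1 + w (N/2-1)/2 (S2 - S1)) / (1 + w (N-1)/2 (S2 - S1)).
```

Their truncation error grows like the product `w N |S1 - S2|`: at
`w = 0.001`, `N = 100` they sit within 0.1% of the exact values, at
`w = 0.01` within roughly 1–5% depending on `|S1 - S2|`. They are
summaries of the weak-selection regime, not substitutes for
`fixation_exact()`, which is itself cheap at any `N` the package targets.

## Parameter conventions and defaults

The defaults throughout mirror the study conditions the package is built
around: `N = 100`, `S2 = 1.5`, `S1` in `{1.25, 1.5, 1.75}` (initially
inferior / neutral / dominant species 1), `w` in `{0.1, 0.9}`, `dt = 0.01`
for positive-feedback experiments and `dt = 0.001` for negative-feedback
sweeps, `a` on `[0, 1]` or `[-1, 0]`, 10000 replicates per estimate, and
balanced initial resources `y0 = 1/2`.

Two conventions deserve comment:

* **Composite-to-raw split.** Figures in this model family are indexed by
  `S_i = c_i/2 + d_i` alone, but the coupled dynamics depend on the raw
  split: `c_i` is the environmental sensitivity of payoff, `d_i` the
  environment-independent part. When a configuration supplies only
  `(S1, S2)`, the package fixes `c1 = c2 = 0.5` and `d_i = S_i - 0.25`.
  Raw `(c, d)` values always take precedence when given. Conclusions that
  hinge on strong feedback should be checked for robustness to this split
  (see the limitations below).
* **`w = 0` is allowed** (pure drift), although the model's motivation is
  weak-but-nonzero selection; the neutral chain is the most valuable
  correctness oracle the package has, so it is a first-class
  configuration rather than an edge case.

All parameters are validated eagerly at construction
(`model_params()`), so a sweep never fails midway on a malformed point;
invalid grid points become error rows in the output table instead.

## The stochastic simulator

`estimate_fixation()` and `early_stage_fitness_proportion()` run replicates
in compiled code. Design points that matter for interpreting results:

* **RNG streams.** Replicate `r` of a run with root seed `s` draws from a
  dedicated `mt19937_64` stream keyed by `(s, r)` only. Estimates are
  therefore bit-reproducible, and extending a run from 2000 to 10000
  replicates reuses the first 2000 outcomes unchanged.
* **Both shares are integrated.** The engine carries `y1` and `y2`
  explicitly and applies the antisymmetric update
  `delta = a y1 y2 (X1 - X2) dt` to both (`y1 += delta`, `y2 -= delta`).
  Algebraically this is identical to folding `y2` into `1 - y1`;
  numerically it is not. A single stored share loses all resolution within
  `2^-53` of 1 while retaining subnormal resolution near 0, which makes
  one environmental boundary effectively absorbing ~20x sooner than the
  other and measurably breaks the model's label-swap symmetry on long
  trajectories (we observed a 16-standard-error asymmetry between mirrored
  configurations before adopting the two-share form; afterwards, mirrored
  estimates agree within Monte-Carlo error, which the test suite checks).
* **Clamping.** Shares are clamped to `[0, 1]` after each Euler step as a
  guard. For `|a| * N * dt <= 1` — which covers every default
  configuration — the unclamped update cannot leave `[0, 1]`, so the clamp
  is provably inactive there (asserted property-style in the tests).
* **Ties.** The early-stage statistic counts replicates with *strictly*
  higher species-1 payoff; ties (for example the exactly neutral
  configuration) count as "not higher".
* **Post-absorption environment.** Once a species fixes, the birth–death
  process stops but the environment does not: early-stage series keep
  advancing `y` under the fixed counts (`X1 - X2 = ±N`). The species
  composition can no longer react, but the fitness-comparison statistic
  remains well defined over the full horizon.
* **Non-absorption is an error.** A replicate that exceeds `max_steps`
  (default 1e7; typical absorption is `O(N^2)` steps) raises a condition
  carrying the replicate index and partial state. Dropping such replicates
  silently would bias fixation estimates toward fast-absorbing outcomes.

`moran_step()` and `simulate_to_fixation()` expose the same process
step-by-step in R (using R's global RNG) for inspection and for tests
that need a trajectory rather than an estimate; the suite checks that the
one-step distribution of the R path matches `transition_probs()` and that
both paths agree with the exact chain at `a = 0`.

## What the experiments show

```{r experiments}
# positive feedback chokes invasion by the dominant species ...
inv <- run_sweep(sweep_spec(a = c(0, 0.5, 1), w = 0.1, S1 = 1.75,
                            scenario = "invasion", n_reps = 2000, seed = 7))
select(inv, a, p_hat, se, preference)
```

Positive feedback makes early abundance self-reinforcing: the resident
majority tilts the environment its own way before the invader can grow,
so the invasion probability collapses with `a` even for a
higher-`S` invader. Negative feedback penalises abundance and does the
opposite. In competition, *both* feedback signs help the initially
inferior species, because demographic luck in the first steps can hand it
the resource advantage — visible directly in the early-stage series:

```{r early}
es <- run_early_stage_experiment(a = c(0, 1), w = 0.1, S1 = 1.25,
                                 n_reps = 2000, seed = 8)
select(es, a, proportion_final)
```

Without feedback the initially inferior species (`S1 = 1.25 < S2 = 1.5`)
*never* holds the fitness lead — the environment is frozen — while under
`a = 1` roughly 40–45% of replicates have handed it the lead by step 500.

## What the generator does and does not emulate

The synthetic experiments implement the model's own assumptions: a
strictly constant population size, exactly one birth–death event per
environmental Euler step, two species and two non-interacting resources,
payoffs linear in the resource share, and no density dependence. Passing
tests demonstrate internal correctness (simulator vs. exact chain,
symmetries, convergence of approximations) and reproduce the model's
qualitative regime structure. They do *not* demonstrate anything about
real populations: fluctuating population sizes, more than two competitors,
resource interactions, or nonlinear payoffs are all outside the model
class, and `dt` is a modelling choice with no empirical calibration.

## Problem sizes used by the test suite

The unit and acceptance tests run the study conditions at reduced
replicate counts — 2000–5000 replicates per stochastic check, which
resolves every tested effect at three binomial standard errors — and the
oracle comparisons use 50 random chains with `N <= 50` where the dense
linear-system solve is exact and fast. `scripts/acceptance.R` re-runs the
headline quantities at the full 10000 replicates; the whole script takes
seconds, because replicates run in compiled code.

## Known limitations

* The with-feedback process admits no exact solution; everything at
  `a != 0` is Monte-Carlo, with binomial standard errors reported
  alongside every estimate.
* The environment uses a fixed-step Euler scheme. At the default
  `|a| N dt <= 1` the scheme is stable and clamp-free, but `dt` is a model
  parameter (the demography/environment timescale ratio), not a numerical
  tolerance: results at different `dt` are different models, not different
  accuracies.
* Strong-feedback, strong-selection regimes are sensitive to the raw
  `(c, d)` split behind a composite sum `S`. Under the default
  `c = 0.5` convention, negative feedback at `w = 0.9` drives the
  initially inferior species' competition fixation probability from
  essentially 0 up to just below `1/2` (0.47–0.49 at
  `a ∈ [-1, -0.1]`, 10000 replicates) without crossing it; a split that
  gives species 2 a larger environmental sensitivity `c2` pushes the same
  statistic higher. Report the split alongside any conclusion in this
  regime.
* Replicates are independent; the package deliberately offers no
  variance-reduction couplings, so comparisons across grid points should
  use the reported standard errors.
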