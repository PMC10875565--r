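# ecomoran

Eco-evolutionary dynamics of a finite two-species population coupled to a
two-resource environment.

## The problem

In a fixed environment, natural selection in a finite population is well
understood: under the Moran birth–death process, the species with higher
fitness fixes with a probability that exceeds the neutral reference
(`1/N` for a lone invader, `1/2` in a fair fight), and that probability has
an exact closed form. But organisms also *change* their environment —
consuming or producing the resources they depend on — and the environment
feeds back into fitness. `ecomoran` implements a minimal model of this
coupling and asks how feedback reshapes which species wins.

The package is for theoretical ecologists and population geneticists who
want exact baselines, reproducible stochastic experiments, and tidy tables
out of a model that is simple enough to reason about: two species, two
resources, one feedback parameter.

## The model

State: `k` individuals of species 1 (out of `N`, fixed) and the share
`y1 ∈ [0,1]` of resource 1 (`y2 = 1 − y1`).

- payoffs: `f_i = c_i y_i + d_i`; fitness: `F_i = 1 − w + w f_i`,
  with selection intensity `w ∈ [0,1]`
- Moran step: birth with probability ∝ fitness, uniform death;
  `p_k⁺ = [kF₁/(kF₁+(N−k)F₂)]·(N−k)/N`, `p_k⁻` symmetric
- environment: `dy₁/dt = a·y₁(1−y₁)(X₁−X₂)`, one Euler step of size `dt`
  per birth–death event; `a > 0` positive feedback, `a < 0` negative
- composite sum `S_i = c_i/2 + d_i` (the payoff at balanced resources)
  decides the feedback-free preference: selection favors species 1 iff
  `S1 > S2`; exact fixation probabilities `ρ_k = (1−γ^k)/(1−γ^N)` with
  `γ = F₂/F₁`, and weak-selection closed forms
  `ρ₁ ≈ (1/N)/(1 + w(N−1)(S₂−S₁)/2)`

Without feedback the chain is solved exactly (`fixation_exact()`); with
feedback (`a ≠ 0`) the coupled system is simulated by a compiled
individual-based engine with per-replicate reproducible RNG streams.

## Worked example

Exact feedback-free baseline for a dominant species 1
(`S1 = 1.75` vs `S2 = 1.5`, `w = 0.1`, `N = 100`):

```r
library(ecomoran)

F1 <- fitness(payoff(0.5, c = 0.5, d = 1.5),  w = 0.1)  # S1 = 1.75
F2 <- fitness(payoff(0.5, c = 0.5, d = 1.25), w = 0.1)  # S2 = 1.5
glance(fixation_exact(100, F1, F2))
#> # A tibble: 1 × 6
#>       N    F1    F2 gamma rho_invasion rho_competition
#>   <int> <dbl> <dbl> <dbl>        <dbl>           <dbl>
#> 1   100  1.08  1.05 0.977       0.0257           0.764
```

A lone dominant invader fixes with probability 0.0257 (2.6× the neutral
1/100); starting from half the population it wins 76.4% of the time.
Now add positive feedback and sweep its intensity in the invasion
scenario:

```r
sw <- run_sweep(sweep_spec(a = c(0, 0.5, 1), w = 0.1, S1 = 1.75,
                           scenario = "invasion", n_reps = 10000, seed = 42))
dplyr::select(sw, a, w, S1, p_hat, se, preference)
#> # A tibble: 3 × 6
#>       a     w    S1  p_hat       se preference
#>   <dbl> <dbl> <dbl>  <dbl>    <dbl>      <dbl>
#> 1   0     0.1  1.75 0.0268 0.00161      0.0168
#> 2   0.5   0.1  1.75 0.003  0.000547    -0.007
#> 3   1     0.1  1.75 0.0019 0.000435    -0.0081
```

At `a = 0` the Monte-Carlo estimate (0.0268 ± 0.0016) agrees with the
exact 0.0257. As feedback strengthens, the resident majority tilts the
environment its own way before the invader can grow: the fixation
probability collapses to 0.0019 and the preference metric
(`ρ̂₁ − 1/N`) turns negative — positive feedback makes even a
fitter species a worse invader than a neutral one. `autoplot(sw)` draws
the preference curve; see the vignette in `vignettes/` for the
competition scenario, negative feedback, and the early-stage
fitness-dominance statistic.

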