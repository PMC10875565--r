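test_that("resource step follows the Euler update and fixes its boundaries", {
  expect_equal(resource_step(0.5, k = 60, N = 100, a = 1, dt = 0.01), 0.55)
  # no feedback leaves the share untouched
  expect_equal(resource_step(0.37, k = 80, N = 100, a = 0, dt = 0.01), 0.37)
  # share boundaries are fixed points of the logistic factor
  expect_equal(resource_step(0, k = 90, N = 100, a = 1, dt = 0.5), 0)
  expect_equal(resource_step(1, k = 10, N = 100, a = -1, dt = 0.5), 1)
  expect_error(resource_step(1.2, 5, 10, 1, 0.01), class = "ecomoran_domain_error")
  expect_error(resource_step(0.5, 11, 10, 1, 0.01), class = "ecomoran_domain_error")
})

test_that("general resource step reduces to the symmetric one and matches direct arithmetic", {
  set.seed(41)
  for (i in 1:15) {
    y <- runif(1); k <- sample(0:50, 1); a <- runif(1, -1, 1); b <- runif(1)
    expect_identical(resource_step_general(y, k, 50, a, b, a, b, 0.01),
                     resource_step(y, k, 50, a, 0.01))
  }
  # null dynamics
  expect_equal(resource_step_general(0.42, 7, 20, 0, 0, 0, 0, 0.01), 0.42)
  # asymmetric-step arithmetic oracle
  expect_equal(resource_step_general(0.5, 50, 100, 1, 0, 0, 0, 0.01),
               0.5 + 0.25 * 50 * 0.01)
})

test_that("the share update is complementary between the two resources", {
  set.seed(43)
  for (i in 1:20) {
    y1 <- runif(1); k <- sample(0:100, 1); a <- runif(1, -1, 1)
    y1_new <- resource_step(y1, k, 100, a, 0.01)
    # resource 2 sees the mirrored counts: X2 - X1 = (N - k) - k
    y2_new <- resource_step(1 - y1, 100 - k, 100, a, 0.01)
    expect_equal(y2_new, 1 - y1_new, tolerance = 1e-15)
  }
})

test_that("the share stays in [0,1] without clamping whenever |a| N dt <= 1", {
  set.seed(47)
  for (i in 1:200) {
    y <- runif(1); k <- sample(0:100, 1); a <- runif(1, -1, 1)
    raw <- y + a * y * (1 - y) * (2 * k - 100) * 0.01 # unclamped update
    expect_true(raw >= 0 && raw <= 1)
    expect_identical(resource_step(y, k, 100, a, 0.01), raw)
  }
})

test_that("moran_step refuses absorbed states and leaves the environment fixed when a = 0", {
  p <- fig_params(a = 0)
  expect_error(moran_step(system_state(0, 0.5, 100), p),
               class = "ecomoran_logic_error")
  expect_error(moran_step(system_state(100, 0.5, 100), p),
               class = "ecomoran_logic_error")
  set.seed(1)
  s <- system_state(50, 0.5, 100)
  for (i in 1:50) {
    s <- moran_step(s, p)
    if (s$k == 0 || s$k == 100) break
  }
  expect_equal(s$y1, 0.5)
  expect_equal(s$step, 50L)
})

test_that("one-step frequencies match the analytic transition probabilities", {
  p <- fig_params(w = 0.1, a = 0, S1 = 1.75, S2 = 1.5)
  tp <- transition_probs(1, 100, balanced_fitness(0.1, 1.75),
                         balanced_fitness(0.1, 1.5))
  n <- 4e4
  set.seed(99)
  moves <- integer(n)
  s0 <- system_state(1, 0.5, 100)
  for (i in seq_len(n)) moves[i] <- moran_step(s0, p)$k - 1L
  for (target in list(c(1, tp$p_up), c(-1, tp$p_down))) {
    phat <- mean(moves == target[1])
    se <- sqrt(target[2] * (1 - target[2]) / n)
    expect_lt(abs(phat - target[2]), 3 * se)
  }
  # neutral midpoint check: both moves near 0.25
  pn <- fig_params(w = 0, a = 0, S1 = 1.5, S2 = 1.5)
  s0 <- system_state(50, 0.5, 100)
  set.seed(100)
  moves <- vapply(seq_len(n), function(i) moran_step(s0, pn)$k - 50L, integer(1))
  expect_lt(abs(mean(moves == 1) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_lt(abs(mean(moves == -1) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("single replicates absorb correctly and report non-absorption loudly", {
  p <- model_params(N = 20, w = 0.1, a = 0, dt = 0.01, S1 = 1.75, S2 = 1.5)
  expect_equal(simulate_to_fixation(p, k0 = 0)$winner, 2L)
  expect_equal(simulate_to_fixation(p, k0 = 0)$steps, 0L)
  expect_equal(simulate_to_fixation(p, k0 = 20)$winner, 1L)
  set.seed(7)
  out <- simulate_to_fixation(p, k0 = 10)
  expect_true(out$winner %in% 1:2)
  expect_gt(out$steps, 0)
  err <- tryCatch(simulate_to_fixation(p, k0 = 10, max_steps = 3),
                  error = function(e) e)
  expect_s3_class(err, "ecomoran_non_absorption")
  expect_equal(err$state$step, 3L) # partial state travels with the error
})

test_that("Monte-Carlo estimates are reproducible and extendable without reshuffling", {
  p <- model_params(N = 30, w = 0.1, a = 0.5, dt = 0.01, S1 = 1.75, S2 = 1.5)
  e1 <- estimate_fixation(p, k0 = 15, n_reps = 300, seed = 5)
  e2 <- estimate_fixation(p, k0 = 15, n_reps = 300, seed = 5)
  expect_identical(tidy(e1), tidy(e2))
  expect_identical(e1$p_hat, e2$p_hat)
  # replicate streams depend only on (seed, r): a longer run extends the shorter
  e3 <- estimate_fixation(p, k0 = 15, n_reps = 500, seed = 5)
  expect_identical(tidy(e3)[1:300, ], tidy(e1))
  # a different seed reshuffles
  e4 <- estimate_fixation(p, k0 = 15, n_reps = 300, seed = 6)
  expect_false(identical(tidy(e4)$winner, tidy(e1)$winner))
})

test_that("without feedback the simulator reproduces neutral and selective fixation probabilities", {
  # neutral k/N identity away from the midpoint
  pn <- fig_params(w = 0.1, a = 0, S1 = 1.5, S2 = 1.5)
  en <- estimate_fixation(pn, k0 = 25, n_reps = 4000, seed = 2)
  expect_lt(abs(en$p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / 4000))
  # neutral symmetry at the midpoint
  em <- estimate_fixation(pn, k0 = 50, n_reps = 4000, seed = 3)
  expect_lt(abs(em$p_hat - 0.5), 3 * sqrt(0.25 / 4000))
  # selective invasion agrees with the exact chain
  ps <- fig_params(w = 0.1, a = 0, S1 = 1.75, S2 = 1.5)
  rho1 <- fixation_exact(100, balanced_fitness(0.1, 1.75),
                         balanced_fitness(0.1, 1.5))$rho[2]
  es <- estimate_fixation(ps, k0 = 1, n_reps = 5000, seed = 4)
  expect_lt(abs(es$p_hat - rho1), 3 * sqrt(rho1 * (1 - rho1) / 5000))
  # with a = 0 the environment never moves
  expect_true(all(tidy(es)$final_y1 == 0.5))
})

test_that("label-swap symmetry holds for the coupled process within Monte-Carlo error", {
  n <- 4000
  p12 <- model_params(N = 100, w = 0.1, a = 1, dt = 0.01, S1 = 1.75, S2 = 1.5)
  p21 <- model_params(N = 100, w = 0.1, a = 1, dt = 0.01, S1 = 1.5, S2 = 1.75)
  e12 <- estimate_fixation(p12, k0 = 30, n_reps = n, seed = 8)
  e21 <- estimate_fixation(p21, k0 = 70, n_reps = n, seed = 9)
  se <- sqrt(e12$p_hat * (1 - e12$p_hat) / n + e21$p_hat * (1 - e21$p_hat) / n)
  expect_lt(abs(e12$p_hat - (1 - e21$p_hat)), 3 * se)
})

test_that("early-stage fitness dominance is null without feedback and responds to feedback", {
  # inferior species, no feedback: shares never move, f1 < f2 throughout
  es0 <- early_stage_fitness_proportion(fig_params(a = 0, S1 = 1.25, S2 = 1.5),
                                        k0 = 50, horizon = 200, n_reps = 500,
                                        seed = 12)
  expect_true(all(es0$proportion_f1_higher == 0))
  # equal composites, no feedback: strict inequality excludes ties
  est <- early_stage_fitness_proportion(fig_params(a = 0, S1 = 1.5, S2 = 1.5),
                                        k0 = 50, horizon = 100, n_reps = 500,
                                        seed = 13)
  expect_true(all(est$proportion_f1_higher == 0))
  # positive feedback lets the inferior species grab the fitness lead
  es1 <- early_stage_fitness_proportion(fig_params(a = 1, S1 = 1.25, S2 = 1.5),
                                        k0 = 50, horizon = 500, n_reps = 2000,
                                        seed = 14)
  expect_gt(es1$proportion_f1_higher[500], 0)
  expect_equal(length(es1$proportion_f1_higher), 500)
  expect_true(all(es1$proportion_f1_higher >= 0 & es1$proportion_f1_higher <= 1))
  td <- tidy(es1)
  expect_equal(nrow(td), 500)
  expect_s3_class(autoplot(es1), "ggplot")
})

test_that("estimate and series objects summarise through glance", {
  p <- model_params(N = 20, w = 0.1, a = 0, dt = 0.01, S1 = 1.75, S2 = 1.5)
  gl <- glance(estimate_fixation(p, k0 = 10, n_reps = 200, seed = 1))
  expect_equal(gl$n_reps, 200L)
  expect_equal(gl$S1, 1.75)
  expect_equal(gl$se, sqrt(gl$p_hat * (1 - gl$p_hat) / 200))
  es <- early_stage_fitness_proportion(p, k0 = 10, horizon = 50, n_reps = 100,
                                       seed = 2)
  expect_equal(glance(es)$proportion_final, es$proportion_f1_higher[50])
})
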