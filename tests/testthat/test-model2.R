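test_that("sigmoid utility has the right inflection, symmetry and bounds", {
  expect_identical(utility(0.5, mu = 2), 2)
  expect_equal(utility(0, mu = 2), 4 / (1 + exp(2.5)))
  # logistic point symmetry about the inflection
  d <- seq(0, 0.5, by = 0.01)
  expect_equal(utility(0.5 + d, 2) + utility(0.5 - d, 2), rep(4, length(d)))
  # strictly increasing, bounded in (0, 2 mu)
  x <- seq(0, 1, by = 0.001)
  w <- utility(x, 2)
  expect_true(all(diff(w) > 0))
  expect_true(all(w > 0 & w < 4))
  expect_error(utility(1.2, 2), "x")
  expect_error(utility(0.5, mu = 0), "mu")
})

test_that("utility is convex below the inflection and concave above", {
  mu <- 2
  x_lo <- seq(0.11, 0.49, by = 0.01)
  gain_lo <- 0.5 * (utility(x_lo + 0.1, mu) + utility(x_lo - 0.1, mu)) -
    utility(x_lo, mu)
  expect_true(all(gain_lo > 0))
  x_hi <- seq(0.51, 0.89, by = 0.01)
  gain_hi <- 0.5 * (utility(x_hi + 0.1, mu) + utility(x_hi - 0.1, mu)) -
    utility(x_hi, mu)
  expect_true(all(gain_hi < 0))
  # a fair +/-0.1 gamble at x = 0.3 beats holding state, in expectation
  expect_gt(0.5 * (utility(0.4, mu) + utility(0.2, mu)), utility(0.3, mu))
})

test_that("only sensitive low-state individuals gamble, with clamping", {
  expect_identical(foraging_step(0.6, TRUE, 1L), 0.6)
  expect_identical(foraging_step(0.5, TRUE, 1L), 0.5)  # boundary: no gamble
  expect_equal(foraging_step(0.3, TRUE, 1L), 0.4)
  expect_equal(foraging_step(0.3, TRUE, 0L), 0.2)
  expect_identical(foraging_step(0.05, TRUE, 0L), 0)   # clamped at 0
  expect_identical(foraging_step(0.3, FALSE, 1L), 0.3) # averse holds
  expect_equal(foraging_step(c(0.3, 0.3, 0.6), rep(TRUE, 3), c(1L, 0L, 1L)),
               c(0.4, 0.2, 0.6))
})

test_that("seasonal totals convert updated states through the utility function", {
  p <- payoff_params(mu = 2)
  g11 <- grain_params(g_r = 1, g_e = 1)

  # variance-averse population, fully coarse grain: every W_i = W(E)
  cfg <- sim_config(n = 1, model = "model2", fitness_scaling = "per_event")
  set.seed(71)
  runif(50)      # the strategy-label draws come first
  E <- runif(1)  # then the global quality the season will draw
  set.seed(71)
  W <- run_season_model2(rep(0, 50), g11, p, cfg)
  expect_equal(W, rep(utility(E, 2), 50))

  # all-sensitive, fully coarse grain, E < 0.5: one shared gamble outcome
  seed <- which.max(vapply(1:50, function(s) {
    set.seed(s); runif(50); u <- runif(1); u > 0.15 && u < 0.45
  }, logical(1)))  # a seed whose drawn E lands in the unclamped gamble zone
  set.seed(seed)
  runif(50)                 # the strategy-label draws
  E <- runif(1)
  set.seed(seed)
  W <- run_season_model2(rep(1, 50), g11, p, cfg)
  expect_equal(length(unique(W)), 1L)
  expect_true(isTRUE(all.equal(W[1], utility(E + 0.1, 2))) ||
                isTRUE(all.equal(W[1], utility(E - 0.1, 2))))
})

test_that("per-event fitness is bounded and scaling keeps totals near mu", {
  p <- payoff_params(mu = 2)
  g <- grain_params(g_r = 0.5, g_e = 0.5)
  set.seed(72)
  W_raw <- run_season_model2(runif(500), g, p,
                             sim_config(n = 10, model = "model2",
                                        fitness_scaling = "per_event"))
  expect_true(all(W_raw < 2 * 2 * 10))
  set.seed(72)
  W_scaled <- run_season_model2(runif(500), g, p,
                                sim_config(n = 10, model = "model2"))
  expect_true(all(W_scaled < 2 * 2))
  expect_equal(W_raw / 10, W_scaled)
})

test_that("across-individual payoff variance shrinks as grain coarsens", {
  p <- payoff_params(mu = 2)
  cfg <- sim_config(n = 1, model = "model2", fitness_scaling = "per_event")
  season_var <- function(g_e, g_r, reps = 50, N = 2000) {
    mean(vapply(seq_len(reps), function(s)
      var(run_season_model2(rep(1, N), grain_params(g_r, g_e), p, cfg)),
      numeric(1)))
  }
  set.seed(73)
  v_ge <- c(season_var(0, 0.5), season_var(0.5, 0.5), season_var(1, 0.5))
  expect_true(all(diff(v_ge) < 0))
  v_gr <- c(season_var(1, 0), season_var(1, 0.5), season_var(1, 1))
  expect_true(all(diff(v_gr) < 0))
  expect_equal(v_gr[3], 0)  # fully shared state and outcome: no spread
})
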