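test_that("populations start at carrying capacity with uniform genes", {
  cfg <- sim_config(K = 5000)
  set.seed(81)
  g <- initialize_population(cfg)
  expect_length(g, 5000)
  expect_true(all(g >= 0 & g <= 1))
  expect_lt(abs(mean(g) - 0.5), 3 * sqrt(1 / 12 / 5000))
  set.seed(81)
  expect_identical(initialize_population(cfg), g)
})

test_that("offspring numbers are proportional to payoffs and unbiased", {
  set.seed(82)
  expect_length(reproduce(0, 0.5), 0L)
  expect_identical(reproduce(9, 0.5), rep(0.5, 9))  # integer payoff: exact
  # stochastic rounding is unbiased: mean offspring of W = 1.8 is 1.8
  counts <- vapply(seq_len(1e5), function(i) length(reproduce(1.8, 0.5)),
                   numeric(1))
  se <- sqrt(0.8 * 0.2 / 1e5)
  expect_lt(abs(mean(counts) - 1.8), 3 * se)
  # offspring inherit the parent's gene exactly
  pool <- reproduce(c(2.2, 3.9), c(0.123, 0.456))
  expect_true(all(pool %in% c(0.123, 0.456)))
  # the Poisson alternative keeps the same expectation
  counts <- vapply(seq_len(1e5), function(i)
    length(reproduce(1.8, 0.5, "poisson")), numeric(1))
  expect_lt(abs(mean(counts) - 1.8), 3 * sqrt(1.8 / 1e5))
})

test_that("between-season mortality is Bernoulli with probability alpha", {
  g <- runif(1e4)
  expect_length(survive_adults(g, alpha = 1), 0L)       # discrete generations
  expect_identical(survive_adults(g, alpha = 0), g)
  set.seed(83)
  n_surv <- length(survive_adults(g, alpha = 0.5))
  expect_lt(abs(n_surv - 5000), 3 * sqrt(1e4 * 0.25))
})

test_that("recruitment fills to carrying capacity, gene-blind", {
  set.seed(84)
  expect_length(recruit(runif(10000), numeric(0), K = 5000), 5000)
  expect_length(recruit(runif(100), numeric(0), K = 5000), 100)
  expect_length(recruit(numeric(0), numeric(0), K = 5000), 0)  # extinction
  nxt <- recruit(runif(6000), runif(2000), K = 5000)
  expect_length(nxt, 5000)

  # hypergeometric gene-blindness: recruited proportion tracks the pool
  pool <- rep(c(0, 1), times = c(7000, 3000))
  rec <- recruit(pool, numeric(0), K = 5000)
  p_hat <- mean(rec)
  se <- sqrt(0.3 * 0.7 / 5000 * (1 - 5000 / 10000))  # finite-pool correction
  expect_lt(abs(p_hat - 0.3), 3 * se)
})

test_that("mutation is rare, Gaussian and clamped to the gene domain", {
  pool <- runif(1000)
  expect_identical(mutate_pool(pool, m_p = 0, m_sigma = 0.05), pool)
  set.seed(85)
  mut <- mutate_pool(rep(0.01, 1e5), m_p = 1, m_sigma = 0.05)
  expect_true(all(mut >= 0))
  expect_gt(mean(mut == 0), 0)  # clamping leaves a point mass at exactly 0
  set.seed(86)
  mut <- mutate_pool(rep(0.5, 1e5), m_p = 1, m_sigma = 0.05)
  expect_lt(abs(sd(mut) - 0.05), 0.001)  # clamping negligible mid-domain
  # only a fraction m_p of offspring are touched
  set.seed(87)
  mut <- mutate_pool(rep(0.5, 1e5), m_p = 0.005, m_sigma = 0.05)
  frac <- mean(mut != 0.5)
  expect_lt(abs(frac - 0.005), 3 * sqrt(0.005 * 0.995 / 1e5))
})

test_that("replicates are deterministic, bounded by K and keep genes in [0,1]", {
  cfg <- sim_config(n = 2, K = 100, seasons = 50, alpha = 0.5)
  g <- grain_params(g_r = 0.5)
  p <- payoff_params()
  r1 <- run_replicate(cfg, g, p, seed = 7, keep_trajectory = TRUE,
                      keep_population = TRUE)
  r2 <- run_replicate(cfg, g, p, seed = 7, keep_trajectory = TRUE,
                      keep_population = TRUE)
  expect_identical(r1, r2)
  expect_true(r1$survived)
  expect_lte(r1$final_N, 100)
  expect_true(all(r1$final_genes >= 0 & r1$final_genes <= 1))
  expect_length(r1$gene_trajectory, 50)

  # zero seasons: the summary reflects the freshly initialized population
  r0 <- run_replicate(sim_config(K = 200, seasons = 0), g, p, seed = 7)
  expect_true(r0$survived)
  expect_equal(r0$final_N, 200)
  expect_equal(r0$seasons_run, 0L)

  # abundant payoffs keep the population pinned at K
  rich <- run_replicate(sim_config(n = 10, K = 100, seasons = 30,
                                   alpha = 1),
                        grain_params(g_r = 0), payoff_params(a = 0),
                        seed = 8)
  expect_equal(rich$final_N, 100)
})

test_that("genes are heritable: without mutation no new values arise", {
  cfg <- sim_config(n = 2, K = 100, seasons = 30, alpha = 0.5, m_p = 0)
  set.seed(90)
  init <- initialize_population(cfg)
  r <- run_replicate(cfg, grain_params(g_r = 0.5), payoff_params(),
                     seed = 90, keep_population = TRUE)
  expect_true(all(r$final_genes %in% init))
})

test_that("extinction is recorded, not raised", {
  # starvation payoffs cannot replace discrete-generation adults
  cfg <- sim_config(n = 1, K = 50, seasons = 100, alpha = 1)
  r <- run_replicate(cfg, grain_params(g_r = 1),
                     payoff_params(mu = 0.05, a = 0, b = 0.5), seed = 9)
  expect_false(r$survived)
  expect_equal(r$final_N, 0L)
  expect_false(is.na(r$extinction_season))
  expect_lte(r$extinction_season, 100)
})

test_that("child seeds are reproducible and spread out", {
  s1 <- child_seed(101, 3, 7)
  expect_identical(s1, child_seed(101, 3, 7))
  seeds <- outer(1:50, 1:50, function(c, r)
    mapply(child_seed, cell = c, replicate = r,
           MoreArgs = list(master_seed = 101)))
  expect_equal(length(unique(as.vector(seeds))), 2500)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
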