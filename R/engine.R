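#' Initialize a population at carrying capacity
#'
#' A population is represented as the numeric vector of its individuals'
#' gene values (probability of playing the variable / variance-sensitive
#' strategy). Initial populations hold `K` individuals with genes drawn
#' i.i.d. Uniform(0, 1).
#'
#' @param config A [sim_config()] object (uses `K`).
#' @return Numeric vector of `K` gene values.
#' @examples
#' set.seed(1)
#' g <- initialize_population(sim_config(K = 100))
#' length(g)
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stats::runif(config$K)
}

#' Produce offspring proportionally to gathered resources
#'
#' Individual `i` with seasonal payoff total `W_i` contributes offspring in
#' proportion to `W_i`. Under the default `"stochastic_round"` rule it gets
#' `floor(W_i)` offspring plus one more with probability `frac(W_i)`, so the
#' expected count equals `W_i` exactly; `"poisson"` draws `Poisson(W_i)`
#' counts instead (same expectation, more variance). Offspring inherit their
#' parent's gene value unchanged (asexual transmission; mutation is a
#' separate step).
#'
#' @param W Numeric vector of non-negative seasonal payoff totals.
#' @param gene Numeric vector of parental gene values, same length as `W`.
#' @param offspring_dist `"stochastic_round"` (default) or `"poisson"`.
#' @return Numeric vector of offspring gene values (the offspring pool; may
#'   be empty).
#' @examples
#' set.seed(1)
#' reproduce(c(0, 2, 1.5), c(0.1, 0.5, 0.9))
#' @export
reproduce <- function(W, gene,
                      offspring_dist = c("stochastic_round", "poisson")) {
  offspring_dist <- match.arg(offspring_dist)
  stopifnot(is.numeric(W), is.numeric(gene), length(W) == length(gene),
            all(W >= 0))
  counts <- if (offspring_dist == "stochastic_round") {
    base <- floor(W)
    base + (stats::runif(length(W)) < W - base)
  } else {
    stats::rpois(length(W), W)
  }
  rep(gene, counts)
}

#' Between-season adult mortality
#'
#' Each adult independently survives the winter with probability
#' `1 - alpha`. `alpha = 1` gives discrete generations (no adult survives);
#' `alpha = 0.5` gives overlapping generations.
#'
#' @param gene Numeric vector of adult gene values.
#' @param alpha Mortality probability, in `[0, 1]`.
#' @return Gene values of the surviving adults (possibly empty).
#' @export
survive_adults <- function(gene, alpha) {
  stopifnot(is.numeric(gene), alpha >= 0, alpha <= 1)
  if (alpha == 1) return(numeric(0))
  if (alpha == 0) return(gene)
  gene[stats::runif(length(gene)) < 1 - alpha]
}

#' Density-regulated recruitment to carrying capacity
#'
#' Juveniles are not density-regulated themselves: recruits are drawn
#' uniformly at random (without replacement, blind to gene value) from the
#' offspring pool to fill the space left under the carrying capacity after
#' adult survival, `min(pool size, max(0, K - survivors))`. The next
#' season's population is survivors plus recruits, so `N <= K` at every
#' season start. Both pools empty means extinction (an empty population,
#' not an error).
#'
#' @param pool Numeric vector of offspring gene values.
#' @param survivors Numeric vector of surviving-adult gene values.
#' @param K Carrying capacity.
#' @return Numeric gene vector of next season's population.
#' @export
recruit <- function(pool, survivors, K) {
  stopifnot(is.numeric(pool), is.numeric(survivors), K >= 1)
  space <- max(0L, K - length(survivors))
  n_rec <- min(length(pool), space)
  recruits <- if (n_rec == 0L) numeric(0)
  else if (n_rec == length(pool)) pool
  else pool[sample.int(length(pool), n_rec)]
  c(survivors, recruits)
}

#' Mutate an offspring pool
#'
#' Each offspring independently mutates with probability `m_p`; a mutation
#' adds a Gaussian deviate with mean 0 and standard deviation `m_sigma` to
#' the gene value, which is then clamped to `[0, 1]` (negative values to 0,
#' values above 1 to 1) since the gene is a probability.
#'
#' @param pool Numeric vector of offspring gene values.
#' @param m_p Per-offspring mutation probability.
#' @param m_sigma Mutational standard deviation.
#' @return Mutated gene vector, same length.
#' @export
mutate_pool <- function(pool, m_p, m_sigma) {
  stopifnot(is.numeric(pool), m_p >= 0, m_p <= 1, m_sigma >= 0)
  if (length(pool) == 0L || m_p == 0) return(pool)
  hit <- which(stats::runif(length(pool)) < m_p)
  if (length(hit)) {
    pool[hit] <- pool[hit] + stats::rnorm(length(hit), 0, m_sigma)
    pool[hit] <- pmin(pmax(pool[hit], 0), 1)
  }
  pool
}

#' Derive a reproducible child seed
#'
#' Hashes `(master_seed, cell, replicate)` into an integer below 2^31 - 1 so
#' every replicate of every parameter combination gets its own reproducible,
#' order-independent random stream: adding cells or replicates never changes
#' the seeds of existing ones.
#'
#' @param master_seed Integer master seed.
#' @param cell Parameter-combination index (default 1).
#' @param replicate Replicate index (default 1).
#' @return A single integer seed.
#' @export
child_seed <- function(master_seed, cell = 1L, replicate = 1L) {
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(as.numeric(master_seed)) + 1) %% m
  s <- (s * 69069 + as.numeric(cell)) %% m
  s <- (s * 69069 + as.numeric(replicate)) %% m
  as.integer(s)
}

#' Run one replicate population to its evolutionary endpoint
#'
#' Iterates the full seasonal lifecycle for `config$seasons` seasons or
#' until extinction: seasonal payoff accumulation under the configured model
#' ([run_season_model1()] or [run_season_model2()]), reproduction
#' proportional to payoff ([reproduce()]), offspring mutation
#' ([mutate_pool()]), between-season adult mortality ([survive_adults()]),
#' and density-regulated recruitment ([recruit()]). The carrying-capacity
#' bound `N <= K` and the gene domain `[0, 1]` are asserted every season.
#'
#' @param config A [sim_config()] object.
#' @param grain A [grain_params()] object.
#' @param params A [payoff_params()] object.
#' @param seed Integer seed for this replicate's random stream (default
#'   derives from `config$master_seed` via [child_seed()]).
#' @param replicate_id Identifier stored in the summary (default 1).
#' @param keep_trajectory If `TRUE`, record the per-season mean gene value.
#' @param keep_population If `TRUE`, include the final gene vector
#'   (`final_genes`) in the summary.
#' @return A `replicate_summary` list with elements `replicate_id`,
#'   `survived`, `extinction_season` (`NA` if survived), `final_mean_gene`,
#'   `final_sd_gene`, `final_N`, `seasons_run` and (optionally)
#'   `gene_trajectory`.
#' @examples
#' cfg <- sim_config(n = 2, K = 50, seasons = 10, replicates = 1)
#' run_replicate(cfg, grain_params(g_r = 0), payoff_params(), seed = 42)
#' @export
run_replicate <- function(config, grain, params,
                          seed = child_seed(config$master_seed),
                          replicate_id = 1L, keep_trajectory = FALSE,
                          keep_population = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(grain, "grain_params"),
            inherits(params, "payoff_params"))
  set.seed(seed)
  season_fun <- switch(config$model,
                       model1 = run_season_model1,
                       model2 = run_season_model2)
  gene <- initialize_population(config)
  traj <- if (keep_trajectory) numeric(config$seasons) else NULL
  extinction_season <- NA_integer_
  s <- 0L
  while (s < config$seasons) {
    s <- s + 1L
    if (length(gene) > config$K || any(gene < 0 | gene > 1))
      stop("population invariant violated at season ", s, call. = FALSE)
    W <- season_fun(gene, grain, params, config)
    pool <- reproduce(W, gene, config$offspring_dist)
    pool <- mutate_pool(pool, config$m_p, config$m_sigma)
    survivors <- survive_adults(gene, config$alpha)
    gene <- recruit(pool, survivors, config$K)
    if (keep_trajectory) traj[s] <- if (length(gene)) mean(gene) else NA_real_
    if (length(gene) == 0L) {
      extinction_season <- s
      break
    }
  }
  out <- list(replicate_id = as.integer(replicate_id),
              survived = length(gene) > 0L,
              extinction_season = extinction_season,
              final_mean_gene = if (length(gene)) mean(gene) else NA_real_,
              final_sd_gene = if (length(gene) > 1L) stats::sd(gene)
                              else NA_real_,
              final_N = length(gene),
              seasons_run = s)
  if (keep_trajectory) out$gene_trajectory <- traj[seq_len(s)]
  if (keep_population) out$final_genes <- gene
  structure(out, class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat("Replicate", x$replicate_id, "-",
      if (x$survived) "survived" else
        paste0("extinct at season ", x$extinction_season), "\n")
  cat("  final N =", x$final_N,
      " mean gene =", signif(x$final_mean_gene, 4),
      " sd gene =", signif(x$final_sd_gene, 4), "\n")
  invisible(x)
}
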