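#' Sigmoid utility: energetic state to fitness resources
#'
#' The logistic map `W(x) = 2 * mu / (1 + exp(-5 * (x - 0.5)))`: strictly
#' increasing, convex below the inflection at `x = 0.5` and concave above it,
#' bounded in `(0, 2 * mu)`, with `W(0.5) = mu`. The convex branch is what
#' makes a fair +/-0.1 gamble on state profitable in expectation for
#' low-state individuals (Jensen's inequality), and the concave branch what
#' makes it costly for high-state ones. The slope (5) and inflection (0.5)
#' are fixed constants of the model.
#'
#' @param x Energetic state(s) in `[0, 1]`.
#' @param mu Expected payoff scale (positive); the upper asymptote is
#'   `2 * mu`.
#' @return Numeric vector of fitness-resource values.
#' @examples
#' utility(0.5, mu = 2)  # exactly 2
#' utility(c(0.4, 0.6), mu = 2)
#' @export
utility <- function(x, mu = 2) {
  stopifnot(is.numeric(x), is.numeric(mu), length(mu) == 1L)
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  if (any(x < 0 | x > 1)) stop("'x' must lie in [0, 1]", call. = FALSE)
  2 * mu / (1 + exp(-5 * (x - 0.5)))
}

#' Variance-sensitive foraging step
#'
#' Variance-sensitive individuals in low state (`x < 0.5`, strictly) gamble
#' at the variable patch: state moves up by 0.1 on success, down by 0.1 on
#' failure, clamped to `[0, 1]`. Everyone else — variance-averse individuals
#' and anyone at `x >= 0.5` — forages at the constant patch and keeps their
#' state unchanged. Vectorised.
#'
#' @param x Numeric vector of states in `[0, 1]`.
#' @param sensitive Logical vector: plays the variance-sensitive strategy.
#' @param success Integer/logical vector: success at the variable patch
#'   (only consulted for gambling individuals).
#' @return Updated state vector.
#' @examples
#' foraging_step(c(0.3, 0.3, 0.6), c(TRUE, TRUE, TRUE), c(1, 0, 1))
#' # 0.4 0.2 0.6
#' @export
foraging_step <- function(x, sensitive, success) {
  stopifnot(is.numeric(x))
  gamble <- sensitive & x < 0.5
  xp <- x + gamble * (0.2 * as.numeric(success) - 0.1)
  xp[xp < 0] <- 0
  xp[xp > 1] <- 1
  xp
}

#' Seasonal payoff accumulation, model 2
#'
#' Runs the `n` decision events of one season under the energetic-state
#' model. Per event: a fresh global environmental quality `E` and individual
#' states are drawn ([sample_states()]); success at the variable patch is
#' drawn with the same grain-correlated machinery as model 1
#' ([sample_resource_conditions()]); variance-sensitive individuals (label
#' drawn per season with probability equal to the gene) in low state take
#' the +/-0.1 gamble ([foraging_step()]); the updated state is converted to
#' fitness resources by [utility()]. Event contributions are divided by `n`
#' under the default `fitness_scaling = "per_event_over_n"` so the expected
#' seasonal total stays near `mu` whatever `n`; `"per_event"` sums raw
#' utilities. States are redrawn from `E` at every event (no carry-over
#' within a season).
#'
#' @inheritParams run_season_model1
#' @return Numeric vector of seasonal payoff totals `W_i`.
#' @examples
#' set.seed(1)
#' run_season_model2(rep(1, 5), grain_params(g_r = 1, g_e = 1),
#'                   payoff_params(), sim_config(n = 1, model = "model2"))
#' @export
run_season_model2 <- function(gene, grain, params, config) {
  stopifnot(length(gene) >= 1, inherits(grain, "grain_params"),
            inherits(params, "payoff_params"), inherits(config, "sim_config"))
  N <- length(gene)
  n <- config$n
  scale <- if (config$fitness_scaling == "per_event_over_n") 1 / n else 1
  # all n events drawn in one batch; distributionally identical to composing
  # sample_states() + sample_resource_conditions() + foraging_step() +
  # utility() event by event
  sensitive <- if (config$per_event_strategy)
    matrix(stats::runif(N * n) < gene, N, n)
  else assign_strategies(gene)
  E <- stats::runif(n)
  lower <- grain$g_e * E
  width <- E + (1 - grain$g_e) * (1 - E) - lower
  x <- rep(lower, each = N) + stats::runif(N * n) * rep(width, each = N)
  dim(x) <- c(N, n)
  Rv <- as.integer(stats::runif(n) >= 0.5)
  match_R <- matrix(stats::runif(N * n) < 0.5 + grain$g_r / 2, N, n)
  r <- match_R * rep(Rv, each = N) + (!match_R) * rep(1L - Rv, each = N)
  gamble <- sensitive & (x < 0.5)
  xp <- x + gamble * (0.2 * r - 0.1)
  xp[xp < 0] <- 0
  xp[xp > 1] <- 1
  U <- 2 * params$mu / (1 + exp(-5 * (xp - 0.5)))
  rowSums(U) * scale
}
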