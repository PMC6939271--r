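#' Payoff geometry of the constant versus variable strategy
#'
#' Bundles the three parameters that define per-event payoffs. The variable
#' strategy pays `mu * (1 - b)` under a bad resource condition and
#' `mu * (1 + b)` under a good one (each condition equally likely overall),
#' so its expected per-event payoff is `mu`. The constant strategy always pays
#' `mu * (1 - a)`: `a` is the proportional penalty accepted for safety, and
#' `b` the proportional variability of the risky option.
#'
#' @param mu Expected per-event payoff of the variable strategy (resource
#'   units). Must be positive. Default 2.
#' @param a Proportional payoff penalty of the constant strategy, in `[0, 1)`.
#'   Default 0.1.
#' @param b Proportional payoff variability of the variable strategy, in
#'   `[0, 1]`. `b = 0` is the degenerate no-variability limit (both strategies
#'   deterministic), useful as a neutrality control when paired with `a = 0`.
#'   Default 0.9.
#'
#' @return An object of class `payoff_params`.
#' @examples
#' payoff_params()                   # mu = 2, a = 0.1, b = 0.9
#' payoff_params(mu = 1, b = 0.5)
#' @export
payoff_params <- function(mu = 2, a = 0.1, b = 0.9) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  if (a < 0 || a >= 1) stop("'a' must lie in [0, 1)", call. = FALSE)
  if (b < 0 || b > 1) stop("'b' must lie in [0, 1]", call. = FALSE)
  structure(list(mu = mu, a = a, b = b), class = "payoff_params")
}

#' Environmental grain parameters
#'
#' Environmental grain controls how strongly stochastic conditions are shared
#' among individuals. `g_r` (grain of resources) sets the correlation in
#' payoff outcomes among individuals playing the variable strategy: each
#' individual's resource condition matches the global state with probability
#' `0.5 + g_r / 2`. `g_e` (grain of the environment) sets the width of the
#' distribution of individual energetic states around the global environmental
#' quality, and is used only by the energetic-state model (model 2).
#'
#' A grain of 1 is a fully coarse-grained environment (everyone shares one
#' outcome); a grain of 0 is fully fine-grained (outcomes independent).
#'
#' @param g_r Grain of resources, in `[0, 1]`. Default 1.
#' @param g_e Grain of the environment, in `[0, 1]`. Default 1.
#'
#' @return An object of class `grain_params`.
#' @examples
#' grain_params(g_r = 0.5)
#' @export
grain_params <- function(g_r = 1, g_e = 1) {
  stopifnot(is.numeric(g_r), length(g_r) == 1L, is.finite(g_r),
            is.numeric(g_e), length(g_e) == 1L, is.finite(g_e))
  if (g_r < 0 || g_r > 1) stop("'g_r' must lie in [0, 1]", call. = FALSE)
  if (g_e < 0 || g_e > 1) stop("'g_e' must lie in [0, 1]", call. = FALSE)
  structure(list(g_r = g_r, g_e = g_e), class = "grain_params")
}

#' Lifecycle and run configuration
#'
#' Collects the demographic and run-control parameters shared by both models:
#' the number of payoff-gathering decision events per season (`n`), the
#' between-season adult mortality (`alpha`; 1 gives discrete generations,
#' 0.5 overlapping), the carrying capacity enforced at the start of each
#' season (`K`), the per-offspring mutation probability and mutational step
#' SD on the gene scale (`m_p`, `m_sigma`), and the run length.
#'
#' Defaults are the baseline study conditions: `K = 5000`, `m_p = 0.005`,
#' `m_sigma = 0.05`, 2000 seasons and 100 replicates.
#'
#' @param n Decision events per season prior to reproduction (positive
#'   integer). Default 1.
#' @param alpha Between-season adult mortality probability, in `[0, 1]`.
#'   Default 1 (discrete generations).
#' @param K Carrying capacity (positive integer). Default 5000.
#' @param m_p Per-offspring mutation probability, in `[0, 1]`. Default 0.005.
#' @param m_sigma Mutation standard deviation on the gene scale
#'   (non-negative). Default 0.05.
#' @param seasons Number of seasons to simulate (non-negative integer).
#'   Default 2000.
#' @param replicates Number of independent replicate populations (positive
#'   integer). Default 100.
#' @param master_seed Integer master seed from which replicate streams are
#'   derived. Default 1.
#' @param model Which per-season payoff model to run: `"model1"` (binary
#'   resource environment) or `"model2"` (energetic states + sigmoid utility).
#' @param fitness_scaling Model-2 only: `"per_event_over_n"` (default) divides
#'   each event's utility by `n` so the expected seasonal total stays near
#'   `mu` regardless of `n`; `"per_event"` accumulates raw utilities.
#' @param offspring_dist How real-valued payoffs are turned into integer
#'   offspring counts: `"stochastic_round"` (default; floor plus a Bernoulli
#'   trial on the fraction, exactly unbiased) or `"poisson"`.
#' @param per_event_strategy If `TRUE`, redraw each individual's strategy
#'   label at every decision event instead of once per season (sensitivity
#'   analysis; default `FALSE`).
#'
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(n = 5, alpha = 0.5, K = 500, seasons = 1000, replicates = 20)
#' @export
sim_config <- function(n = 1, alpha = 1, K = 5000, m_p = 0.005,
                       m_sigma = 0.05, seasons = 2000, replicates = 100,
                       master_seed = 1,
                       model = c("model1", "model2"),
                       fitness_scaling = c("per_event_over_n", "per_event"),
                       offspring_dist = c("stochastic_round", "poisson"),
                       per_event_strategy = FALSE) {
  model <- match.arg(model)
  fitness_scaling <- match.arg(fitness_scaling)
  offspring_dist <- match.arg(offspring_dist)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == round(n),
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(K), length(K) == 1L, K >= 1, K == round(K),
            is.numeric(m_p), length(m_p) == 1L,
            is.numeric(m_sigma), length(m_sigma) == 1L, m_sigma >= 0,
            is.numeric(seasons), length(seasons) == 1L, seasons >= 0,
            seasons == round(seasons),
            is.numeric(replicates), length(replicates) == 1L, replicates >= 1,
            replicates == round(replicates),
            is.numeric(master_seed), length(master_seed) == 1L,
            is.logical(per_event_strategy), length(per_event_strategy) == 1L)
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]", call. = FALSE)
  if (m_p < 0 || m_p > 1) stop("'m_p' must lie in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), alpha = alpha, K = as.integer(K),
                 m_p = m_p, m_sigma = m_sigma,
                 seasons = as.integer(seasons),
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed),
                 model = model, fitness_scaling = fitness_scaling,
                 offspring_dist = offspring_dist,
                 per_event_strategy = per_event_strategy),
            class = "sim_config")
}

#' @export
print.payoff_params <- function(x, ...) {
  cat("Payoff parameters: mu =", x$mu, " a =", x$a, " b =", x$b, "\n")
  cat("  constant strategy pays", x$mu * (1 - x$a),
      "; variable strategy pays", x$mu * (1 - x$b), "or", x$mu * (1 + x$b),
      "\n")
  invisible(x)
}

#' @export
print.grain_params <- function(x, ...) {
  cat("Environmental grain: g_r =", x$g_r, " g_e =", x$g_e, "\n")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (", x$model, "):\n", sep = "")
  cat("  n =", x$n, " alpha =", x$alpha, " K =", x$K, "\n")
  cat("  m_p =", x$m_p, " m_sigma =", x$m_sigma, "\n")
  cat("  seasons =", x$seasons, " replicates =", x$replicates,
      " master_seed =", x$master_seed, "\n")
  if (x$model == "model2")
    cat("  fitness_scaling =", x$fitness_scaling, "\n")
  invisible(x)
}
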