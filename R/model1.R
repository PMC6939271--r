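#' Assign strategies from gene values
#'
#' Each individual carries a gene giving its probability of playing the
#' variable (variance-prone) strategy; labels are drawn independently from
#' those probabilities. By default the engine draws labels once per season
#' and holds them across all `n` decision events.
#'
#' @param gene Numeric vector of gene values in `[0, 1]`.
#' @return Logical vector: `TRUE` = variable strategy, `FALSE` = constant.
#' @examples
#' set.seed(1)
#' assign_strategies(c(0, 1, 0.5))
#' @export
assign_strategies <- function(gene) {
  stopifnot(is.numeric(gene))
  stats::runif(length(gene)) < gene
}

#' Per-event payoff under the binary resource environment
#'
#' The constant strategy pays `mu * (1 - a)` regardless of conditions; the
#' variable strategy pays `mu * (1 - b)` when the local resource condition is
#' bad (`r_i = 0`) and `mu * (1 + b)` when good (`r_i = 1`). Vectorised over
#' `variable` and `r_i`.
#'
#' @param variable Logical (vector): `TRUE` for the variable strategy.
#' @param r_i Integer (vector) of local resource conditions, 0 or 1. Ignored
#'   for constant players.
#' @param params A [payoff_params()] object.
#' @return Numeric payoff(s).
#' @examples
#' p <- payoff_params(mu = 2, a = 0.1, b = 0.9)
#' event_payoff(FALSE, 0, p)  # 1.8
#' event_payoff(TRUE, 0, p)   # 0.2
#' event_payoff(TRUE, 1, p)   # 3.8
#' @export
event_payoff <- function(variable, r_i, params) {
  stopifnot(inherits(params, "payoff_params"), is.logical(variable))
  if (any(r_i != 0 & r_i != 1)) stop("'r_i' must be 0 or 1", call. = FALSE)
  w_var <- params$mu * (1 - params$b + 2 * params$b * r_i)
  w_const <- params$mu * (1 - params$a)
  variable * w_var + (!variable) * w_const
}

#' Seasonal payoff accumulation, model 1
#'
#' Runs the `n` independent decision events of one season for a population of
#' gene values: strategy labels are drawn (once per season unless
#' `config$per_event_strategy`), then for each event a fresh resource draw
#' ([sample_resource_conditions()]) determines each variable player's payoff.
#' Payoffs accumulate additively within the season.
#'
#' @param gene Numeric vector of gene values in `[0, 1]` (the population).
#' @param grain A [grain_params()] object (only `g_r` is used).
#' @param params A [payoff_params()] object.
#' @param config A [sim_config()] object (uses `n`, `per_event_strategy`).
#' @return Numeric vector of seasonal payoff totals `W_i`, same length as
#'   `gene`.
#' @examples
#' set.seed(1)
#' run_season_model1(rep(1, 5), grain_params(g_r = 1), payoff_params(),
#'                   sim_config(n = 1))
#' @export
run_season_model1 <- function(gene, grain, params, config) {
  stopifnot(length(gene) >= 1, inherits(grain, "grain_params"),
            inherits(params, "payoff_params"), inherits(config, "sim_config"))
  N <- length(gene)
  n <- config$n
  mu <- params$mu
  # all n events drawn in one batch; distributionally identical to composing
  # sample_resource_conditions() + event_payoff() event by event
  variable <- assign_strategies(gene)
  Rv <- as.integer(stats::runif(n) >= 0.5)          # global state per event
  match_R <- matrix(stats::runif(N * n) < 0.5 + grain$g_r / 2, N, n)
  r <- match_R * rep(Rv, each = N) + (!match_R) * rep(1L - Rv, each = N)
  if (config$per_event_strategy) {
    lab <- matrix(stats::runif(N * n) < gene, N, n)
    per_event <- lab * (mu * (1 - params$b + 2 * params$b * r)) +
      (!lab) * (mu * (1 - params$a))
    return(rowSums(per_event))
  }
  successes <- rowSums(r)
  w_var <- n * mu * (1 - params$b) + 2 * mu * params$b * successes
  w_const <- n * mu * (1 - params$a)
  variable * w_var + (!variable) * w_const
}
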