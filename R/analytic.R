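#' Weighted geometric-mean lifetime payoff of the variable strategy
#'
#' Long-term (lineage) payoff of playing the variable strategy for all `n`
#' decision events of a season when payoffs are fully correlated among
#' individuals (coarse-grained environment, `g_r = 1`), so that fitness
#' accumulates multiplicatively across seasons. With `m` of the `n` events
#' successful, the seasonal total is `mu * ((1-b)(n-m) + (1+b)m)`; the lineage
#' payoff is the product of these totals over `m = 0..n`, each raised to its
#' binomial probability `choose(n, m) / 2^n` — a probability-weighted
#' geometric mean.
#'
#' Computed in log space with exact log-binomial weights ([lchoose()]), so
#' large `n` neither overflows nor loses the weights' precision. When `b = 1`
#' the all-failure season has total payoff 0, which drags the whole geometric
#' mean to exactly 0; that case returns 0 rather than an error.
#'
#' @param mu Expected per-event payoff of the variable strategy (positive).
#' @param b Proportional payoff variability, in `[0, 1]` (`b = 0` is the
#'   degenerate limit where the geometric mean equals the arithmetic mean
#'   `mu * n`).
#' @param n Number of decision events per season (positive integer).
#'
#' @return The weighted geometric-mean seasonal payoff (scalar).
#' @seealso [max_safe_penalty()], [constant_lifetime_payoff()]
#' @examples
#' geometric_mean_variable(mu = 1, b = 0.9, n = 1)  # sqrt(0.1 * 1.9)
#' geometric_mean_variable(mu = 2, b = 0, n = 5)    # 10: no variability
#' @export
geometric_mean_variable <- function(mu, b, n) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  if (b < 0 || b > 1) stop("'b' must lie in [0, 1]", call. = FALSE)
  m <- 0:n
  total <- (1 - b) * (n - m) + (1 + b) * m  # seasonal payoff total / mu
  if (any(total == 0)) return(0)            # b = 1, m = 0: log-domain -Inf
  logw <- lchoose(n, m) - n * log(2)        # log binomial weights, exact
  mu * exp(sum(exp(logw) * log(total)))
}

#' Lifetime payoff of the constant strategy
#'
#' Seasonal payoff total of playing the safe, constant strategy for all `n`
#' events: `mu * n * (1 - a)`. Deterministic, so its geometric and arithmetic
#' means coincide.
#'
#' @inheritParams geometric_mean_variable
#' @param a Proportional payoff penalty of the constant strategy, in
#'   `[0, 1)`.
#' @return The seasonal payoff total (scalar).
#' @examples
#' constant_lifetime_payoff(mu = 2, a = 0.1, n = 1)  # 1.8
#' @export
constant_lifetime_payoff <- function(mu, a, n) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  if (a < 0 || a >= 1) stop("'a' must lie in [0, 1)", call. = FALSE)
  mu * n * (1 - a)
}

#' Maximum safe-strategy penalty favouring the constant strategy
#'
#' The largest proportional penalty `a` at which the constant strategy still
#' has higher long-term lineage payoff than the variable strategy under fully
#' correlated payoffs (`g_r = 1`):
#' `a* = 1 - G_var(n, b) / (mu * n)`, which is independent of `mu`. The
#' constant strategy is favoured iff `a < a*`.
#'
#' @inheritParams geometric_mean_variable
#' @return The penalty bound `a*`, a scalar in `[0, 1)`.
#' @examples
#' max_safe_penalty(b = 0.9, n = 1)  # 1 - sqrt(0.19), about 0.564
#' max_safe_penalty(b = 0.9, n = 5)  # about 0.11; the two strategies are
#'                                   # nearly equal at a = 0.1
#' @export
max_safe_penalty <- function(b, n) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(n), length(n) == 1L, n >= 1, n == round(n))
  if (b < 0 || b > 1) stop("'b' must lie in [0, 1]", call. = FALSE)
  1 - geometric_mean_variable(mu = 1, b = b, n = n) / n
}

#' Penalty-bound surface over a (b, n) grid
#'
#' Evaluates [max_safe_penalty()] on the outer product of variability values
#' `b_values` and event counts `n_values`, in long format suitable for
#' contour plotting or CSV export. The bound rises with `b` (more variability
#' tolerates a larger safety penalty) and falls with `n` (additive
#' accumulation over more events erodes the bet-hedging advantage).
#'
#' @param b_values Numeric vector of variability fractions in `(0, 1]`.
#'   Default `seq(0.05, 1, by = 0.05)`.
#' @param n_values Integer vector of event counts (all >= 1). Default `1:10`.
#'
#' @return A data.frame with columns `b`, `n` and `a_max`, one row per grid
#'   cell, of class `penalty_bound_grid`.
#' @examples
#' penalty_bound_grid(b_values = c(0.5, 0.9), n_values = c(1, 5))
#' @export
penalty_bound_grid <- function(b_values = seq(0.05, 1, by = 0.05),
                               n_values = 1:10) {
  stopifnot(length(b_values) >= 1, length(n_values) >= 1,
            all(b_values > 0), all(b_values <= 1),
            all(n_values >= 1), all(n_values == round(n_values)))
  grid <- expand.grid(b = b_values, n = as.integer(n_values),
                      KEEP.OUT.ATTRS = FALSE)
  grid$a_max <- mapply(max_safe_penalty, b = grid$b, n = grid$n)
  class(grid) <- c("penalty_bound_grid", "data.frame")
  grid
}

#' Contour plot of the penalty-bound surface
#'
#' @param grid A data.frame from [penalty_bound_grid()].
#' @return A ggplot object.
#' @export
plot_penalty_bound <- function(grid) {
  stopifnot(all(c("b", "n", "a_max") %in% names(grid)))
  ggplot2::ggplot(grid, ggplot2::aes(x = n, y = b, z = a_max)) +
    ggplot2::geom_contour_filled(bins = 10) +
    ggplot2::labs(x = "decision events per season (n)",
                  y = "payoff variability (b)",
                  fill = "max safe penalty a*") +
    ggplot2::theme_minimal()
}
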