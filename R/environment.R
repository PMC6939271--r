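#' Sample grain-correlated resource conditions
#'
#' Draws one global resource state `R` (good = 1 or bad = 0, equal
#' probability) and a per-individual resource condition vector `r`: each
#' individual independently experiences the global state with probability
#' `0.5 + g_r / 2` and the opposite state otherwise. At `g_r = 1` every
#' individual shares the global state; at `g_r = 0` conditions are
#' independent coin flips.
#'
#' Consumes the global random-number stream; seed with [set.seed()] (the
#' engine does this per replicate) for reproducibility.
#'
#' @param g_r Grain of resources, in `[0, 1]`.
#' @param N Number of individuals (positive integer).
#'
#' @return A list with elements `R` (integer scalar, 0 or 1) and `r`
#'   (integer vector of length `N`, each 0 or 1).
#' @examples
#' set.seed(1)
#' sample_resource_conditions(g_r = 0.5, N = 10)
#' @export
sample_resource_conditions <- function(g_r, N) {
  if (!is.numeric(g_r) || length(g_r) != 1L || is.na(g_r) ||
      g_r < 0 || g_r > 1)
    stop("'g_r' must be a single value in [0, 1]", call. = FALSE)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  N <- as.integer(N)
  R <- if (stats::runif(1L) < 0.5) 0L else 1L
  match_R <- stats::runif(N) < 0.5 + g_r / 2
  r <- if (R == 1L) as.integer(match_R) else as.integer(!match_R)
  list(R = R, r = r)
}

#' Sample grain-correlated energetic states
#'
#' Draws one global environmental quality `E ~ Uniform(0, 1)` and `N`
#' individual energetic states uniformly on the interval
#' `[g_e * E, E + (1 - g_e) * (1 - E)]`. The interval always contains `E`
#' and narrows linearly onto it as `g_e` grows: at `g_e = 1` every state
#' equals `E`; at `g_e = 0` states span the whole unit interval.
#'
#' Consumes the global random-number stream, like
#' [sample_resource_conditions()].
#'
#' @param g_e Grain of the environment, in `[0, 1]`.
#' @param N Number of individuals (positive integer).
#'
#' @return A list with elements `E` (scalar in `[0, 1]`) and `x` (numeric
#'   vector of length `N` of states in `[0, 1]`).
#' @examples
#' set.seed(1)
#' sample_states(g_e = 0.5, N = 5)
#' @export
sample_states <- function(g_e, N) {
  if (!is.numeric(g_e) || length(g_e) != 1L || is.na(g_e) ||
      g_e < 0 || g_e > 1)
    stop("'g_e' must be a single value in [0, 1]", call. = FALSE)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  N <- as.integer(N)
  E <- stats::runif(1L)
  lower <- g_e * E
  upper <- E + (1 - g_e) * (1 - E)
  x <- stats::runif(N, min = lower, max = upper)
  list(E = E, x = x)
}

#' Bounds of the energetic-state distribution
#'
#' Returns the interval from which individual states are drawn for a given
#' global environmental quality `E` and grain `g_e`.
#'
#' @param g_e Grain of the environment, in `[0, 1]`.
#' @param E Global environmental quality, in `[0, 1]`.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' state_bounds(g_e = 0.5, E = 0.4)  # c(0.2, 0.7)
#' @export
state_bounds <- function(g_e, E) {
  stopifnot(g_e >= 0, g_e <= 1, E >= 0, E <= 1)
  c(g_e * E, E + (1 - g_e) * (1 - E))
}
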