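# Independent oracles for the closed-form fitness analysis.

# Exhaustive enumeration of all 2^n equiprobable success/failure sequences:
# seasonal total payoff per sequence, then the geometric mean of the totals
# (all sequences equally likely, weight 2^-n each).
enum_geometric_mean <- function(mu, b, n) {
  stopifnot(n <= 16)
  seqs <- expand.grid(rep(list(c(0L, 1L)), n))
  totals <- apply(seqs, 1L, function(ev)
    sum(mu * (1 - b) * (ev == 0) + mu * (1 + b) * (ev == 1)))
  if (any(totals == 0)) return(0)
  exp(mean(log(totals)))
}

# Monte-Carlo lineage-growth oracle: many generations of multiplicative
# accumulation of the seasonal total payoff at fully correlated outcomes.
# Returns the per-generation growth factor and the standard error of its log.
mc_geometric_mean <- function(mu, b, n, generations = 1e6) {
  m <- stats::rbinom(generations, n, 0.5)
  totals <- mu * ((1 - b) * (n - m) + (1 + b) * m)
  logs <- log(totals)
  list(G = exp(mean(logs)), se_log = stats::sd(logs) / sqrt(generations))
}

# Scaled-down sweep conditions reused across endpoint-pattern tests.
scaled_config <- function(..., K = 500, seasons = 1000, replicates = 20,
                          master_seed = 101) {
  sim_config(..., K = K, seasons = seasons, replicates = replicates,
             master_seed = master_seed)
}
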