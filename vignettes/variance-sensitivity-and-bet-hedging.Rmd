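---
title: "Variance-sensitive strategies under bet-hedging selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-sensitive strategies under bet-hedging selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bethedge)
```

## The question

Should an organism prefer a safe option with a predictable, slightly reduced
payoff, or a risky option with the same expected payoff but high variance?
Classic variance-sensitivity theory answers at the individual level: if the
utility function mapping resources to fitness is convex, gamble; if concave,
play safe. Bet-hedging theory answers at the lineage level: reproduction
compounds multiplicatively across generations, so long-term success follows
the *geometric* mean of fitness across generations, which punishes variance —
a genotype can profit from "playing it safe" even at a cost to its arithmetic
mean fitness (conservative bet-hedging).

Which force wins depends on two quantities this package makes explicit:

* **`n`, the number of decision events per lifetime.** Payoffs accumulate
  additively *within* a lifetime; the variance of an average of `n`
  independent gambles shrinks as `n` grows, so many events shift the balance
  toward arithmetic accumulation and risk proneness.
* **Environmental grain, `g_r` and `g_e` in `[0, 1]`.** Grain measures how
  strongly stochastic outcomes are shared among individuals. In a
  coarse-grained environment (grain near 1) all gamblers win or lose
  together, so their genotype's mean fitness fluctuates across generations —
  exactly the variance the geometric mean punishes. In a fine-grained
  environment (grain near 0) outcomes are independent and average out across
  the population within each generation, leaving little genotype-level
  variance for bet-hedging to act on.

## The analytic baseline

With fully correlated payoffs (`g_r = 1`), a lineage playing the variable
strategy every event has long-term seasonal payoff given by a
probability-weighted geometric mean over the number of successful events
`m = 0..n`, each season's total raised to its binomial weight:

$$G_{\mathrm{var},n} \;=\; \mu \prod_{m=0}^{n}
  \Big[(1-b)(n-m) + (1+b)m\Big]^{\binom{n}{m} 0.5^n},$$

where the variable strategy pays $\mu(1-b)$ per bad event and $\mu(1+b)$ per
good one. The constant strategy pays $\mu(1-a)$ per event, deterministically,
so $G_{\mathrm{const},n} = \mu n (1-a)$. Setting
$G_{\mathrm{const},n} > G_{\mathrm{var},n}$ and solving for `a` gives the
largest safety penalty still favouring the safe strategy:

$$a^\* \;=\; 1 - \frac{1}{n}\prod_{m=0}^{n}
  \Big[(1-b)(n-m) + (1+b)m\Big]^{\binom{n}{m} 0.5^n},$$

independent of $\mu$. `geometric_mean_variable()`, `max_safe_penalty()` and
`penalty_bound_grid()` implement these. Everything is computed as the
exponential of a weighted sum of logs, with log-binomial weights from
`lchoose()`, so the products neither overflow nor lose precision at large
`n`. Two degenerate cases are handled explicitly: `b = 0` collapses the
geometric mean onto the arithmetic mean $\mu n$ (so $a^\* = 0$), and `b = 1`
puts zero payoff on the all-failure season, which drags the whole geometric
mean — and hence `geometric_mean_variable()` — to exactly 0 and $a^\*$ to 1.

```{r}
max_safe_penalty(b = 0.9, n = 5)
vapply(c(1, 2, 5, 10), max_safe_penalty, numeric(1), b = 0.9)
```

At the baseline payoff geometry (`mu = 2`, `a = 0.1`, `b = 0.9`) the bound
passes almost exactly through `a = 0.1` at `n = 5`: the two strategies are
then nearly equal in long-term fitness, so simulations are expected to tip
toward the safe strategy for `n < 5` and toward the risky one for `n > 5`
as the environment coarsens. A note on this formula's direction: the bound
$a^\*$ *decreases* with `n` — with more events per lifetime, only a small
safety penalty is compatible with the safe strategy still winning — which is
the quantitative face of additive accumulation eroding the bet-hedging
advantage. Our simulations confirm this direction.

## Model 1: binary resource environment

Each of the `n` events draws a global state `R` (good/bad, probability 0.5
each), and each individual's local condition matches `R` with probability
`0.5 + g_r/2` (`sample_resource_conditions()`). Individuals carry a gene in
`[0, 1]`: their probability of playing the variable strategy. Payoffs follow
`event_payoff()` and sum over the season's events.

## Model 2: energetic states and a sigmoid utility

Model 2 adds the machinery that classical risk-sensitivity theory assumes.
Each event draws a global environmental quality `E ~ Uniform(0, 1)`; each
individual's energetic state is uniform on
`[g_e * E, E + (1 - g_e)(1 - E)]` (`sample_states()`), an interval that
always contains `E`, lies inside `[0, 1]`, and narrows onto `E` as `g_e`
grows. Variance-sensitive individuals (probability = gene) in low state
(`x < 0.5`, strictly; `x = 0.5` exactly counts as high) gamble at a variable
patch: state moves ±0.1, success driven by the same grain-correlated
machinery as model 1. Everyone else holds state. The updated state converts
to fitness through the sigmoid utility

$$W(x) = \frac{2\mu}{1 + e^{-5(x - 0.5)}},$$

convex below `x = 0.5` and concave above, so the gamble is
arithmetically favourable exactly for the low-state individuals who take it.

## The lifecycle engine

Per season: payoff accumulation (model 1 or 2) → reproduction proportional
to the seasonal total (`reproduce()`) → offspring mutation (`mutate_pool()`)
→ adult mortality with probability `alpha` (`survive_adults()`) →
gene-blind recruitment from the offspring pool up to carrying capacity
(`recruit()`). Populations start at `K` with uniform genes. `N ≤ K` at
every season start and gene values staying in `[0, 1]` are asserted during
simulation; extinction (`N = 0`) is a recorded outcome, never an error.

Several points of the lifecycle are underdetermined by the verbal model, and
the package fixes them as follows:

* **Offspring integerization.** Seasonal payoffs are real numbers but
  offspring are discrete. Default is unbiased stochastic rounding
  (`floor(W)` plus a Bernoulli trial on the fraction), so expected offspring
  equal `W` exactly; a `Poisson(W)` alternative sits behind
  `offspring_dist = "poisson"`. Both make reproduction exactly proportional
  to gathered resources in expectation.
* **Recruitment.** Recruits are drawn uniformly without replacement from the
  offspring pool to fill `max(0, K - survivors)` places; juveniles are not
  density-regulated, and winter totals may exceed `K` as long as the next
  season starts at or below it.
* **Mortality order.** Mortality strikes adults after reproduction;
  orphaned offspring recruit normally.
* **Distribution of `E`.** Uniform on its stated support `[0, 1]` (the
  maximum-entropy choice), redrawn independently at every decision event, as
  is the resource state `R`.
* **Strategy labels** are drawn once per individual per season and held for
  all `n` events — the gene is a whole-organism strategy, not an
  event-by-event coin. A per-event redraw is available
  (`per_event_strategy = TRUE`) for sensitivity analysis.
* **No state carry-over** between events in model 2: each event draws
  states afresh from `E`; each is a complete draw–gamble–convert cycle. The
  ±0.1 step is clamped to `[0, 1]` to preserve the utility's domain.
* **State and resource draws are independent** sources of stochasticity in
  model 2 (`E` does not influence gamble success).
* **Fitness scaling.** Under the default
  `fitness_scaling = "per_event_over_n"` each event contributes `W(x')/n`,
  keeping the expected seasonal total near `mu` for every `n` (so `mu`
  retains its meaning of a mean reproductive rate, and recruit numbers and
  extinction risk are comparable across `n`). Raw per-event accumulation is
  available as `"per_event"`; within a season the two differ only by a
  common factor, so relative fitness is unchanged.
* **Payoff variability domain.** `b` is nominally in `(0, 1]`; the
  constructors also admit `b = 0`, the degenerate no-variability limit,
  because the payoff-identical configuration `a = 0, b = 0` is the natural
  neutrality control for the whole engine (drift alone should leave the mean
  gene near 0.5, and does — see the test suite).

## Randomness and reproducibility

All sampling uses R's global Mersenne–Twister stream. `run_replicate()`
seeds it once per replicate; `run_sweep()` derives that seed from
`(master_seed, cell index, replicate index)` via `child_seed()`, an integer
hash below $2^{31}$. Replicates are therefore reproducible independently of
execution order, and extending a grid never changes existing cells. Within a
season, the `n` events' draws are generated in one vectorized batch,
distributionally identical to drawing event by event.

## Problem sizes

The full study conditions (`K = 5000`, 2000 seasons, 100 replicates per
cell) are the package defaults. The test suite and examples run a
scaled-down standard — `K = 500`, 1000 seasons, 20 replicates — chosen
because the mutation–selection–drift balance at `m_p = 0.005`,
`m_sigma = 0.05` equilibrates well before season 1000 under the baseline
selection differentials, so endpoint patterns are already stable; the
neutrality control scales further (`K = 200`, 500 seasons, 50 replicates)
since it only needs the drift distribution around 0.5. At this scale the
across-replicate SDs are larger than at the full scale (drift is stronger
at small `K`), which the pattern checks accommodate by testing orderings
and thresholds, not point values.

## What the simulations emulate — and what they do not

The generator reproduces the study system faithfully: i.i.d. environments
across seasons, binary or continuous global states, grain-controlled
correlation among individuals, asexual inheritance of a single continuous
gene. It does *not* emulate autocorrelated environments, spatially explicit
patches, sexual reproduction or diploidy, age structure, or state carry-over
across events — so passing tests say nothing about systems where, for
example, bad years cluster in time or condition persists within a lifetime.
Endpoint checks in the tests are ordering/threshold properties of the
evolved gene surface (which cells are risk-prone, which risk-averse, which
flat), not numeric endpoint values.

## Known limitations

* At small `K` the drift variance across replicates is substantial;
  cells under weak selection (e.g. near the `n = 5`, `g_r = 1` balance
  point, or model 2 at large `n`) show wide across-replicate spreads.
* The analytic bound applies only to the fully correlated case `g_r = 1`;
  for intermediate grain the simulator is the only route.
* Model-2 extinction risk depends on absolute recruit numbers and hence on
  `K` and the fitness scaling; scaled-down runs underestimate how often
  small, coarse-grained populations die out at full scale.
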