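Package: bethedge
Title: Individual-Based Simulation of Variance-Sensitive Strategies Under
    Bet-Hedging Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when short-term variance-prone (risk-prone)
    strategies are outcompeted by conservative bet-hedging in stochastic
    environments. Provides the closed-form weighted geometric-mean fitness of a
    variable versus a constant payoff strategy and the resulting penalty bound
    separating them, two individual-based evolutionary models (a binary-quality
    resource environment, and an energetic-state model with a sigmoid utility
    function), a shared mutation-selection-drift lifecycle engine with
    density-regulated recruitment, and a parameter-sweep experiment runner with
    tidy CSV output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
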