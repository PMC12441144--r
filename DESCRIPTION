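Package: riskysocial
Title: Bayesian Belief-Updating Models of Social Influence on Risky Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian estimation of a cognitive
    model of social influence on risky choice in which internal uncertainty
    about outcome probabilities is represented by beta-distribution
    pseudo-counts and social information enters as weighted Bayesian
    updating.  Includes a lottery task-design generator (decisions from
    description vs. experience, with predetermined marble sample sequences),
    forward simulation of age-structured synthetic participant populations
    with risk-prone advisor matching, penalized maximum a posteriori and
    Metropolis-within-Gibbs hierarchical fitting with split-chain R-hat
    diagnostics, Pareto-smoothed importance-sampling leave-one-trial-out
    cross-validation (looic) for model comparison, parameter- and
    model-recovery suites, and susceptibility-to-social-influence metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
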