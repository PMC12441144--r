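# riskysocial

Bayesian belief-updating models of social influence on risky choice.

## What this is for

Developmental and decision scientists studying *why* people — adolescents in
particular — follow others when choosing between a safe and a risky option.
The package implements a cognitive model in which susceptibility to social
influence emerges from two separable sources: **internal uncertainty** about
a lottery's win probability, represented as beta-distribution pseudo-counts,
and **social sensitivity**, the weight given to one piece of advice. It
provides the full study pipeline around that model: a marble-jar lottery
task generator (decisions from description vs. experience), forward
simulation of age-structured synthetic participants with risk-prone advisor
matching, penalized-MAP and hierarchical MCMC estimation, PSIS
leave-one-trial-out model comparison (looic), parameter/model recovery
suites, and susceptibility metrics.

## The model

For a lottery paying `V` points with probability `p` against a safe 5
points:

* utility `U = V^ρ`;
* belief `φ ~ Beta(α, β)` with `α = p·κ`, `β = (1−p)·κ` — `κ` is the total
  pseudo-count ("how many marbles the subject acts as if they saw"), with
  separate `κ_desc` / `κ_exp` per condition;
* advice adds `ψ` pseudo-counts to the favoured side:
  `p′ = (α + SI_risk·ψ_risky) / (α + SI_risk·ψ_risky + β + SI_safe·ψ_safe)`,
  so shifts are large exactly when `κ` is small — uncertainty amplifies
  social influence; `ψ = 1` is an ideal Bayesian observer, `ψ = 0` ignores
  advice;
* choice `cp = 1 / (1 + exp(−(EU_risk − EU_safe)/τ))` with
  `EU_risk = p′·V^ρ`, `EU_safe = 5^ρ`.

The nested variants `m0` (utility only), `m1` (ideal Bayesian), `m2s`
(single `ψ`) and `m2` (separate safe/risky `ψ`) are compared by looic.

## Worked example

```r
library(riskysocial)
library(dplyr)

design <- build_design(seed = 1)          # 144 trials, 8 per (V, p) cell
pop    <- simulate_population(6, seed = 1)
study  <- simulate_study(pop, design, seed = 1)

study$matches
#> # A tibble: 6 × 3
#>   subject_id advisor_id excess
#>   <chr>      <chr>       <int>
#> 1 S001       A047            8
#> 2 S002       A047           12
#> 3 S003       A020           15
#> 4 S004       A020           14
#> 5 S005       A047           11
#> 6 S006       A047           14

susceptibility(pop, study$choices) %>%
  group_by(condition, advice) %>%
  summarise(shift = mean(signed_shift), .groups = "drop")
#> # A tibble: 4 × 3
#>   condition   advice  shift
#>   <chr>       <chr>   <dbl>
#> 1 description risky   0.227
#> 2 description safe   -0.149
#> 3 experience  risky   0.234
#> 4 experience  safe   -0.182
```

Each advisor made up to 15 more risky first-half choices than the subject
(relaxed in integer steps where no exact match exists — the `excess`
column), and beliefs shift toward the advised jar, by more under
experience, where internal uncertainty is higher. A shift of 0.2 means the
subject acts as if the advised jar were 20 percentage points more likely
to pay out.

Fitting and comparing models:

```r
fit  <- fit_hierarchical(study$choices, pop, "m2", mcmc_config(), seed = 1)
tidy(fit)                       # per-subject posterior summaries
group_means(fit)                # age-group-level means
m0 <- fit_map(study$choices, "m0", seed = 1)
m2 <- fit_map(study$choices, "m2", seed = 1)
compare_variants(list(m0 = m0, m2 = m2))
```

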