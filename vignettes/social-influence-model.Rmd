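---
title: "Modelling social influence on risky choice as belief updating under internal uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling social influence on risky choice as belief updating under internal uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskysocial)
library(dplyr)
```

## The problem

Adolescents are widely held to be more susceptible to social influence than
children or adults, and the usual explanations appeal to heightened reward
sensitivity or social motivation. An alternative is simpler: people follow
others more when they are *uncertain* about what to do, and young people may
carry more internal uncertainty about the utility of their options.
`riskysocial` implements a computational account that separates these
ingredients in a lottery task, and everything needed to study it end to end:
the task design, forward simulation of synthetic participant populations,
hierarchical Bayesian estimation, leave-one-trial-out model comparison, and
recovery suites.

## The task

Each of 144 trials offers a *safe jar* that always pays 5 points and a
*risky jar* that pays `V` points (8, 20 or 50) with probability `p` (0.125
to 0.75 in steps of 0.125); every value-probability combination repeats
eight times in randomised order. External uncertainty is manipulated by
condition: in *description* trials the probability is displayed exactly; in
*experience* trials it must be inferred from nine predetermined marble
samples. Samples are chosen to be as representative of `p` as possible: the
blue-marble count is the nearest integer to `9p` (round-half-to-even), and
at exact `.5` ties the floor and ceiling alternate across repetitions so
that a cell's average sample composition equals `p` exactly. In the second
half of the session, each trial displays the choice of an advisor drawn
from a pool of risk-prone agents, matched so that the advisor made about 15
more risky first-half choices than the participant (relaxed one integer at
a time when no exact match exists).

## The model

Choices arise from four components:

1. **Utility.** Point values are transformed by a power function
   `U = V^rho`; `rho < 1` is risk-averse curvature, `rho > 1` risk-seeking.
2. **Internal uncertainty.** The belief about the win probability is a beta
   distribution with mean `p` and total pseudo-count `kappa`, i.e.
   `alpha = p * kappa` pseudo-successes and `beta = (1 - p) * kappa`
   pseudo-failures. A subject with `kappa = 2` acts as if their entire
   knowledge of the jar were two marbles; `kappa = 20` acts as if it were
   twenty. `kappa` takes separate values in description and experience
   trials (`kappa_desc`, `kappa_exp`), because external uncertainty should
   raise internal uncertainty only where probabilities must be inferred.
3. **Social updating.** Advice adds `psi` pseudo-counts to the favoured
   side: `p' = (alpha + SI_risk * psi_risky) / (alpha + SI_risk * psi_risky
   + beta + SI_safe * psi_safe)`. `psi = 1` is an ideal Bayesian observer
   (one observed choice counts as one marble); `psi = 0` ignores advice.
   By Bayes' rule the induced shift `|p' - p|` shrinks as `kappa` grows —
   internal uncertainty and social sensitivity jointly produce
   susceptibility to social influence.
4. **Choice.** A logistic rule on the expected-utility difference,
   `cp = 1 / (1 + exp(-(EU_risk - EU_safe) / tau))`, with
   `EU_risk = p' * V^rho` and `EU_safe = 5^rho` (the safe jar is certain,
   so it carries no belief distribution). Higher temperature `tau` means
   noisier choices. Because expected utilities scale with `V^rho`, `tau`
   and `rho` trade off; the priors keep both identified.

The nested variant family (`model_variants()`) switches these components
off one at a time: `m0` (utility only), `m1` (ideal Bayesian, `psi = 1`),
`m2s` (one free `psi`), `m2` (separate safe/risky sensitivities). `m2` with
`psi = 0` reproduces `m0` and with `psi = 1` reproduces `m1` exactly,
which the tests assert bitwise.

```{r core}
belief <- prior_belief(0.5, 2)
social_update(belief, "risky", psi_safe = 1, psi_risky = 1) # ideal observer
social_update(prior_belief(0.5, 20), "risky", 1, 1)         # less uncertain
```

## The synthetic population

The generator stands in for the study population the analyses assume: 166
subjects aged 10-26 (ages uniform over the range), 144 trials each, with
age-graded parameters. Parameters are log-Normal around a linear predictor
in standardized age polynomials (mean 0, SD 0.5, the convention used for
all continuous covariates). The default trends encode the developmental
structure of interest: internal uncertainty under experience falls with age
(positive slope on `log kappa_exp`), social sensitivities and temperature
fall with age (negative linear and quadratic slopes), reward sensitivity is
near-flat, and `kappa_desc` is age-invariant.

The default magnitudes were fixed once by calibration simulation before the
test suite was written, under two constraints: the population must
reproduce the qualitative signatures (risky choice declining with age,
advice moving choices in its own direction, susceptibility larger under
experience than description and smaller in older agents), and the
parameters must be identifiable from 144 trials per subject — a recovery
demonstration on a non-identifiable design would be vacuous. Identifiability
of `psi_safe` is the binding constraint: a risk-prone advisor produces only
about 17-25 safe-advice trials per subject, so the defaults use substantial
between-subject heterogeneity in social sensitivity (log-SD 1.1-1.3,
spanning near-copyists to advice-ignorers) and a choice temperature low
enough that belief shifts show up in choices. For the same reason the
advisor pool is simulated with human-scale choice noise (`tau = 4`): a
near-deterministic advisor gives safe advice only on lotteries that every
agent already declines, which destroys the information those trials carry
about `psi_safe`. These are deliberately strong-effect conditions chosen
for a clean test bed; passing tests on them shows the pipeline recovers
structure that is present, not that effects of this size exist in any real
population. Other simplifications relative to real data: ages are uniform
rather than recruitment-weighted, there are no probability-estimate
sliders, reaction times, or dropped trials, and advisor identity has no
behavioural consequence beyond the advice labels.

```{r sim}
pop <- simulate_population(6, seed = 1)
design <- build_design(seed = 1)
study <- simulate_study(pop, design, seed = 1)
head(study$choices)
study$matches
```

## Estimation

Two paths expose the same likelihood (asserted equal to `trial_loglik()`
to 1e-8):

* `fit_subject_map()` / `fit_map()` — penalized maximum a posteriori on the
  log-parameter scale, best of several multistarts, with a Laplace
  approximation around the mode so that even the fast path yields a
  draws-by-trials pointwise log-likelihood matrix for cross-validation.
  Degenerate data (all choices identical) and bound-hugging estimates are
  flagged rather than silently returned.
* `fit_hierarchical()` — subject parameters drawn from Normal group-level
  distributions per age group (default tertile-style bins 10-13, 14-17,
  18-26; the exact recruitment bins of any particular study are
  configurable). Sampling is adaptive Metropolis-within-Gibbs:
  per-coordinate random-walk updates of subject parameters evaluated in one
  vectorised pass across subjects, conjugate Gibbs updates for group means,
  and log-scale random walks for group SDs. Split-chain R-hat is recorded
  for every sampled quantity; any value above 1.01 (deliberately stricter
  than the conventional 1.0 to catch scaled-down pathologies) attaches a
  convergence warning.

Default priors are weakly informative on transformed scales —
`log kappa ~ N(log 5, 1)`, `log tau ~ N(0, 1)`, `log rho ~ N(0, 0.5)`,
`psi ~ half-Normal(0, 2)` — and overridable via `prior_config()`. The
`"desk"` MCMC preset (4 chains x 2000 iterations, 1000 warmup) is sized for
simulation studies on one CPU: a 40-subject full-model fit takes about a
minute. Convergence checks during development showed that half that chain
length leaves subject-level R-hats well above the threshold, which set the
preset. The `"paper"` preset (4 x 6000, 2000 warmup) matches the scale a
full analysis would use.

Numerical choices: choice probabilities are clipped to `[1e-9, 1 - 1e-9]`
inside the likelihood; the logistic uses `plogis()`; the optimizer works in
a `[-7, 7]` box on the log scale and non-finite objective values (utility
overflow at extreme `rho`) are mapped to a large penalty; Hessians are
symmetrized and ridge-repaired before inversion.

## Model comparison

`loo_from_pointwise()` implements approximate leave-one-trial-out
cross-validation by Pareto-smoothed importance sampling: raw importance
log-weights are the negative pointwise log-likelihoods, the largest 20% are
replaced by expected order statistics of a generalized Pareto distribution
fitted by the Zhang-Stephens profile likelihood, and observations with tail
shape above 0.7 are flagged as unreliable (flagged, never silently
replaced). `looic = -2 * elpd_loo`. The trial, not the subject, is the unit
of cross-validation. A single-row matrix (point fit) falls back to the
in-sample sum and is flagged as non-Bayesian. The implementation is checked
in the tests against a brute-force oracle that refits the posterior once
per left-out trial on a 20-trial dataset.

`compare_variants()` tabulates elpd with pairwise differences to the best
variant (SE from the paired pointwise differences), and `model_recovery()`
runs the simulate-fit-compare loop to produce a confusion matrix. On the
MAP path the Laplace draws are what gives LOO its complexity penalty; with
pure point estimates the largest nested model would always win in-sample.

## Behavioural metrics

`susceptibility()` computes the per-subject mean `|p' - p|` by condition
and advice type — a value of 0.2 means the subject acted as if the advised
jar were 20 percentage points more likely to pay out. The same quantity
computed from true generative parameters and from a converged fit agrees
within recovery tolerance, which the tests assert. `summarize_behaviour()`
gives risky-choice proportions by age bin, condition and advice with
bootstrap 95% intervals; the bootstrap resamples subjects, not trials,
respecting the repeated-measures structure (1000 resamples by default).
`fit_age_trend()` regresses per-subject parameter values (log scale by
default) on standardized linear and quadratic age polynomials.

```{r metrics}
susceptibility(pop, study$choices) %>%
  group_by(condition, advice) %>%
  summarise(shift = mean(signed_shift), .groups = "drop")
```

## Design decisions and limitations

* **Open question — trial ordering.** How description/experience trials
  interleave with the solo/social halves is not constrained beyond social
  information appearing only in the second half; the generator balances
  conditions within both halves so every cell is crossed, which maximises
  design information. The split is configurable through the design config.
* **Open question — which trials enter the fit.** All 144 trials enter the
  likelihood: solo trials identify `rho` and `tau` (and leave `kappa`
  untouched — the likelihood is exactly flat in `kappa` on solo data, which
  a test asserts), social trials add `kappa` and `psi`.
* **Advisor labels.** Advice on a social trial equals the matched advisor's
  simulated choice on that same trial; how advisor choices mapped to trials
  in any real session is underdetermined, and same-trial mapping is the
  cleanest cell-matched choice.
* **`psi` upper bound.** Social sensitivities are unbounded above with a
  half-Normal prior; hard caps would truncate the near-copyist regime the
  population deliberately contains.
* **Susceptibility aggregation.** The absolute shift `|p' - p|` is averaged
  per subject within condition and advice type, as stated; the signed shift
  is reported alongside for direction checks.
* **Known limitations.** The sampler is random-walk based, so `"desk"`-size
  runs on strongly correlated posteriors can flag R-hat warnings —
  lengthen chains rather than trust flagged output. Per-subject maximum a
  posteriori estimates of `psi_safe` are information-limited by the small
  number of safe-advice trials; the hierarchical fit is the supported route
  to population-level conclusions. Parameter recovery is demonstrated under
  the generator's strong-effect defaults, not for arbitrarily weak effects.
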