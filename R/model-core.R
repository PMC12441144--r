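#' Power utility of a point value
#'
#' Transforms lottery point values into subjective utility with a power
#' function, `U = V^rho`.  Exponents below 1 give a concave (risk-averse)
#' utility, above 1 a convex (risk-seeking) one.
#'
#' @param value Numeric vector of point values (non-negative).
#' @param rho Utility exponent, strictly positive.
#' @return Numeric vector of utilities.
#' @examples
#' utility(50, 0.5)
#' @export
utility <- function(value, rho) {
  if (any(value < 0)) rs_abort("`value` must be non-negative.", "rs_domain_error")
  if (any(rho <= 0)) rs_abort("`rho` must be strictly positive.", "rs_domain_error")
  value^rho
}

#' Prior belief about a win probability as beta pseudo-counts
#'
#' Represents internal uncertainty about a lottery's win probability as a
#' beta distribution with mean `p_win` and total pseudo-count `kappa`:
#' `alpha = p_win * kappa` pseudo-successes (blue marbles) and
#' `beta = (1 - p_win) * kappa` pseudo-failures (red marbles).  A `kappa`
#' of 2 behaves as if the decision maker had seen two marbles; larger
#' `kappa` means less internal uncertainty.
#'
#' @param p_win Win probability, strictly inside (0, 1).  Vectorised.
#' @param kappa Pseudo-count rate, strictly positive.  Vectorised.
#' @return A tibble with columns `alpha`, `beta`, `p_prior`.
#' @examples
#' prior_belief(0.75, 20)
#' @export
prior_belief <- function(p_win, kappa) {
  if (any(p_win <= 0 | p_win >= 1)) {
    rs_abort("`p_win` must lie strictly inside (0, 1).", "rs_domain_error")
  }
  if (any(kappa <= 0)) rs_abort("`kappa` must be strictly positive.", "rs_domain_error")
  tibble(
    alpha   = p_win * kappa,
    beta    = (1 - p_win) * kappa,
    p_prior = p_win
  )
}

#' Update a belief with social information
#'
#' Adds `psi` pseudo-counts to the pseudo-successes when advice favours the
#' risky option, or to the pseudo-failures when it favours the safe option,
#' and returns the posterior mean
#' `p' = (alpha + SI_risk * psi_risky) / (alpha + SI_risk * psi_risky + beta + SI_safe * psi_safe)`.
#' `psi = 1` is the ideal Bayesian observer (one observed choice counts as
#' one marble); `psi = 0` ignores advice entirely.
#'
#' @param belief A tibble as returned by [prior_belief()] (columns `alpha`,
#'   `beta`), or any data frame with those columns.
#' @param social Character vector in `c("none", "safe", "risky")`.
#' @param psi_safe,psi_risky Social-sensitivity weights, non-negative.
#' @return Numeric vector of post-advice means `p'`.
#' @examples
#' social_update(prior_belief(0.5, 2), "risky", 1, 1)
#' @export
social_update <- function(belief, social, psi_safe = 1, psi_risky = 1) {
  if (any(psi_safe < 0) || any(psi_risky < 0)) {
    rs_abort("social-sensitivity weights must be non-negative.", "rs_domain_error")
  }
  if (!all(social %in% c("none", "safe", "risky"))) {
    rs_abort("`social` must be one of 'none', 'safe', 'risky'.", "rs_domain_error")
  }
  si_risk <- as.numeric(social == "risky")
  si_safe <- as.numeric(social == "safe")
  a <- belief$alpha + si_risk * psi_risky
  b <- belief$beta + si_safe * psi_safe
  a / (a + b)
}

#' Expected utilities of the risky and safe options
#'
#' Combines the belief, social update and utility stages for a table of
#' trials: `EU_risk = p' * value_risky^rho` and `EU_safe = safe_value^rho`
#' (the safe jar pays its value with certainty).
#'
#' @param trials A data frame with columns `value_risky`, `p_win`,
#'   `condition` (`"description"`/`"experience"`), `social`, `safe_value`.
#' @param params Named list or vector of agent parameters (`rho`,
#'   `kappa_desc`, `kappa_exp`, `psi_safe`, `psi_risky`, `tau`).
#' @param variant Model variant id, see [model_variants()].
#' @return The trials tibble with extra columns `p_prior`, `p_post`,
#'   `eu_risk`, `eu_safe`.
#' @export
expected_utilities <- function(trials, params, variant = "m2") {
  v <- variant_spec(variant)
  params <- canonical_params(params, variant)
  kappa <- ifelse(trials$condition == "experience", params$kappa_exp, params$kappa_desc)
  belief <- prior_belief(trials$p_win, kappa)
  social <- if (v$uses_social) trials$social else rep("none", nrow(trials))
  social[is.na(social)] <- "none"
  p_post <- social_update(belief, social, params$psi_safe, params$psi_risky)
  trials %>%
    mutate(
      p_prior = belief$p_prior,
      p_post  = p_post,
      eu_risk = p_post * utility(.data$value_risky, params$rho),
      eu_safe = utility(.data$safe_value, params$rho)
    )
}

#' Softmax probability of choosing the risky option
#'
#' Logistic choice rule on the expected-utility difference with a
#' temperature parameter: `cp = 1 / (1 + exp(-(eu_risk - eu_safe) / tau))`.
#' Higher temperatures give more random choices; as `tau` grows the
#' probability approaches 0.5.
#'
#' @param eu_risk,eu_safe Expected utilities (numeric vectors).
#' @param tau Temperature, strictly positive.
#' @return Probabilities of a risky choice in (0, 1).
#' @examples
#' choice_probability(6, 5, 1)
#' @export
choice_probability <- function(eu_risk, eu_safe, tau) {
  if (any(tau <= 0)) rs_abort("`tau` must be strictly positive.", "rs_domain_error")
  plogis((eu_risk - eu_safe) / tau)
}

# cp for a whole trial table under a variant; returns numeric vector
choice_prob_trials <- function(trials, params, variant = "m2") {
  eus <- expected_utilities(trials, params, variant)
  choice_probability(eus$eu_risk, eus$eu_safe, canonical_params(params, variant)$tau)
}

#' Bernoulli log-likelihood of observed choices
#'
#' Per-trial log-likelihood under a model variant: `log(cp)` for a risky
#' choice (coded 1) and `log(1 - cp)` for a safe choice (coded 0), with
#' `cp` clipped to `[1e-9, 1 - 1e-9]` before taking logs.
#'
#' @param trials Trial table (see [expected_utilities()]) with a `choice`
#'   column coded 1 = risky, 0 = safe.
#' @param params Agent parameters.
#' @param variant Model variant id.
#' @return Numeric vector of per-trial log-likelihood contributions.
#' @export
trial_loglik <- function(trials, params, variant = "m2") {
  if (!all(trials$choice %in% c(0, 1))) {
    rs_abort("`choice` must be coded 0 (safe) or 1 (risky).", "rs_domain_error")
  }
  cp <- choice_prob_trials(trials, params, variant)
  cp <- pmin(pmax(cp, 1e-9), 1 - 1e-9)
  ifelse(trials$choice == 1, log(cp), log1p(-cp))
}

# ---- model-variant registry ------------------------------------------------

.variants <- list(
  m0 = list(
    label = "utility-only (social information ignored)",
    free = c("rho", "tau"),
    uses_social = FALSE
  ),
  m1 = list(
    label = "ideal Bayesian observer (psi fixed at 1)",
    free = c("rho", "kappa_desc", "kappa_exp", "tau"),
    uses_social = TRUE
  ),
  m2 = list(
    label = "full model (separate safe/risky social sensitivity)",
    free = c("rho", "kappa_desc", "kappa_exp", "psi_safe", "psi_risky", "tau"),
    uses_social = TRUE
  ),
  m2s = list(
    label = "single social sensitivity (psi_safe = psi_risky)",
    free = c("rho", "kappa_desc", "kappa_exp", "psi", "tau"),
    uses_social = TRUE
  )
)

#' Registry of nested model variants
#'
#' The candidate family is nested: `m0` fits only reward sensitivity and
#' temperature (advice has no effect); `m1` adds condition-specific internal
#' uncertainty with an implicit social weight of 1 (ideal Bayesian); `m2s`
#' frees a single social-sensitivity weight; `m2` splits that weight by safe
#' vs. risky advice.
#'
#' @return A tibble with one row per variant: `variant`, `label`,
#'   `n_free`, `free` (list-column of free parameter names).
#' @export
model_variants <- function() {
  tibble(
    variant = names(.variants),
    label = purrr::map_chr(.variants, "label"),
    n_free = purrr::map_int(.variants, ~ length(.x$free)),
    free = purrr::map(.variants, "free")
  )
}

variant_spec <- function(variant) {
  if (!variant %in% names(.variants)) {
    rs_abort(paste0("unknown model variant '", variant, "'."), "rs_config_error")
  }
  c(.variants[[variant]], list(variant = variant))
}

# Fill in the full 6-parameter set implied by a variant from its free
# parameters: m0 pins psi at 0 (kappa then drops out of the likelihood;
# set to 1 for definiteness), m1 pins psi at 1, m2s ties psi_safe=psi_risky.
canonical_params <- function(params, variant = "m2") {
  v <- variant_spec(variant)
  p <- as.list(params)
  missing <- setdiff(v$free, names(p))
  if (length(missing) > 0) {
    rs_abort(paste0("missing parameter(s): ", paste(missing, collapse = ", ")),
             "rs_config_error")
  }
  out <- switch(v$variant,
    m0  = list(rho = p$rho, kappa_desc = 1, kappa_exp = 1,
               psi_safe = 0, psi_risky = 0, tau = p$tau),
    m1  = list(rho = p$rho, kappa_desc = p$kappa_desc, kappa_exp = p$kappa_exp,
               psi_safe = 1, psi_risky = 1, tau = p$tau),
    m2  = p[c("rho", "kappa_desc", "kappa_exp", "psi_safe", "psi_risky", "tau")],
    m2s = list(rho = p$rho, kappa_desc = p$kappa_desc, kappa_exp = p$kappa_exp,
               psi_safe = p$psi, psi_risky = p$psi, tau = p$tau)
  )
  bad <- vapply(out[c("rho", "kappa_desc", "kappa_exp", "tau")],
                function(x) !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) rs_abort("rho, kappa and tau must be finite and positive.", "rs_domain_error")
  if (out$psi_safe < 0 || out$psi_risky < 0) {
    rs_abort("psi must be non-negative.", "rs_domain_error")
  }
  out
}
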