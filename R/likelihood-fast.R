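# Internal fast likelihood path used by the fitters.
#
# The user-facing trial_loglik() works on tibbles and is convenient for
# analysis; optimizers and samplers evaluate the likelihood hundreds of
# thousands of times, so the trial table is pre-compiled once into plain
# numeric vectors and the per-evaluation work is pure arithmetic.  A test
# asserts equality with trial_loglik() to 1e-8.

prep_trials <- function(trials, variant = "m2") {
  v <- variant_spec(variant)
  social <- trials$social
  if (!v$uses_social) social <- rep("none", nrow(trials))
  social[is.na(social)] <- "none"
  list(
    v = trials$value_risky,
    p = trials$p_win,
    safe = trials$safe_value,
    is_exp = trials$condition == "experience",
    si_r = as.numeric(social == "risky"),
    si_s = as.numeric(social == "safe"),
    y = if ("choice" %in% names(trials)) trials$choice else NULL,
    n = nrow(trials)
  )
}

# pointwise log-likelihood given natural-scale canonical parameters (each a
# scalar or an n-vector, enabling vectorisation across subjects)
fast_loglik <- function(prep, rho, kappa_desc, kappa_exp, psi_safe, psi_risky, tau) {
  kappa <- ifelse(prep$is_exp, kappa_exp, kappa_desc)
  a <- prep$p * kappa + prep$si_r * psi_risky
  b <- (1 - prep$p) * kappa + prep$si_s * psi_safe
  p_post <- a / (a + b)
  eu_diff <- p_post * prep$v^rho - prep$safe^rho
  cp <- plogis(eu_diff / tau)
  cp <- pmin(pmax(cp, 1e-9), 1 - 1e-9)
  ifelse(prep$y == 1, log(cp), log1p(-cp))
}

# sum log-likelihood for one subject's transformed free-parameter vector
theta_loglik <- function(theta, prep, variant) {
  pars <- canonical_params(theta_to_params(theta, variant), variant)
  sum(fast_loglik(prep, pars$rho, pars$kappa_desc, pars$kappa_exp,
                  pars$psi_safe, pars$psi_risky, pars$tau))
}

theta_pointwise <- function(theta, prep, variant) {
  pars <- canonical_params(theta_to_params(theta, variant), variant)
  fast_loglik(prep, pars$rho, pars$kappa_desc, pars$kappa_exp,
              pars$psi_safe, pars$psi_risky, pars$tau)
}
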