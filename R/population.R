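#' Age-trend configuration for the synthetic population
#'
#' Each agent parameter is generated on a transformed (log) scale as a
#' linear function of standardized linear and quadratic age polynomials
#' (mean 0, SD 0.5) plus Normal between-subject dispersion:
#' `log theta = intercept + b_lin * age_lin + b_quad * age_quad + e`.
#' The defaults encode the qualitative developmental structure the model is
#' built around: internal uncertainty in the experience condition falls with
#' age (positive slope on log kappa_exp), social sensitivity and choice
#' temperature fall with age (negative linear and quadratic slopes on
#' log psi and log tau), reward sensitivity is near-flat, and internal
#' uncertainty from description is age-invariant.  Intercepts put the
#' typical agent at rho just below 1 (mild risk aversion), kappa of a few
#' marbles' worth of pseudo-evidence, psi near the ideal-Bayesian 1, and a
#' temperature that leaves choices stochastic but value-driven.
#'
#' @param age_range Years; subjects are drawn uniformly over this range.
#' @param n_trials_expected Unused placeholder kept for config round-trips.
#' @param params A named list overriding per-parameter entries; each entry
#'   is `list(intercept =, b_lin =, b_quad =, sd =)` on the log scale.
#' @return A list of class `rs_age_model`.
#' @export
age_trend_config <- function(age_range = c(10, 26), params = list(),
                             n_trials_expected = NULL) {
  defaults <- list(
    rho        = list(intercept = log(0.88), b_lin = -0.12, b_quad = 0,     sd = 0.15),
    kappa_desc = list(intercept = log(3),    b_lin = 0,     b_quad = 0,     sd = 0.60),
    kappa_exp  = list(intercept = log(2),    b_lin = 1.30,  b_quad = 0,     sd = 0.80),
    psi_safe   = list(intercept = log(3),    b_lin = -1.20, b_quad = -0.45, sd = 1.30),
    psi_risky  = list(intercept = log(2),    b_lin = -0.90, b_quad = -0.35, sd = 1.10),
    tau        = list(intercept = log(0.8),  b_lin = -0.50, b_quad = -0.20, sd = 0.50)
  )
  for (nm in names(params)) {
    if (!nm %in% names(defaults)) {
      rs_abort(paste0("unknown parameter '", nm, "' in age model."), "rs_config_error")
    }
    defaults[[nm]] <- modifyList(defaults[[nm]], params[[nm]])
  }
  bad <- vapply(defaults, function(x) x$sd < 0, logical(1))
  if (any(bad)) rs_abort("age-model dispersions must be non-negative.", "rs_config_error")
  structure(list(age_range = age_range, params = defaults), class = "rs_age_model")
}

# standardize to mean 0, SD 0.5 (the convention used for all continuous
# covariates in the analyses)
standardize_half <- function(x) {
  s <- sd(x)
  if (s == 0) rs_abort("cannot standardize a constant variable.", "rs_rank_error")
  0.5 * (x - mean(x)) / s
}

#' Simulate a synthetic participant population
#'
#' Draws ages uniformly over the configured range, builds standardized
#' linear and quadratic age polynomials (mean 0, SD 0.5), assigns age-group
#' labels used as hierarchical hyperprior groups, and generates each
#' subject's true model parameters from the age-trend model.
#'
#' @param n_subjects Number of subjects (the study emulated has 166).
#' @param age_model An [age_trend_config()] object.
#' @param seed Integer seed.
#' @param age_breaks Right-closed break points defining age groups
#'   (defaults to 10-13, 14-17, 18-26).
#' @return A tibble with columns `subject_id`, `age`, `age_lin`, `age_quad`,
#'   `group`, and the true parameters `rho`, `kappa_desc`, `kappa_exp`,
#'   `psi_safe`, `psi_risky`, `tau`.
#' @examples
#' simulate_population(8, seed = 1)
#' @export
simulate_population <- function(n_subjects = 166, age_model = age_trend_config(),
                                seed = 1, age_breaks = c(10, 13.99, 17.99, 26)) {
  if (!inherits(age_model, "rs_age_model")) {
    rs_abort("`age_model` must be an age_trend_config().", "rs_config_error")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  age <- sort(runif(n_subjects, age_model$age_range[1], age_model$age_range[2]))
  age_lin <- standardize_half(age)
  age_quad <- standardize_half((age - mean(age))^2)
  group <- cut(age, breaks = age_breaks, include.lowest = TRUE,
               labels = paste0("G", seq_len(length(age_breaks) - 1)))
  out <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    age = age, age_lin = age_lin, age_quad = age_quad,
    group = as.character(group)
  )
  for (nm in names(age_model$params)) {
    cfg <- age_model$params[[nm]]
    mu <- cfg$intercept + cfg$b_lin * age_lin + cfg$b_quad * age_quad
    out[[nm]] <- exp(rnorm(n_subjects, mu, cfg$sd))
  }
  out
}
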