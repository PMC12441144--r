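#' Prior configuration for model fitting
#'
#' Weakly-informative priors on the transformed (log) parameter scales used
#' by both the penalized-MAP and the MCMC fitters: `log kappa ~ N(log 5, 1)`
#' (centred on "five marbles" of pseudo-evidence), `log tau ~ N(0, 1)`,
#' `log rho ~ N(0, 0.5)` (centred on risk neutrality), and a
#' `half-Normal(0, 2)` prior on the natural scale of the social
#' sensitivities `psi` (the Jacobian of the log transform is included when
#' sampling or optimizing on `log psi`).
#'
#' @param ... Named overrides; each entry is `list(mean =, sd =)` for the
#'   log-Normal parameters (`rho`, `kappa_desc`, `kappa_exp`, `tau`) or
#'   `list(sd =)` for the half-Normal `psi` entries (`psi_safe`,
#'   `psi_risky`, `psi`).
#' @return A list of class `rs_priors`.
#' @export
prior_config <- function(...) {
  defaults <- list(
    rho        = list(type = "lognormal", mean = 0,      sd = 0.5),
    kappa_desc = list(type = "lognormal", mean = log(5), sd = 1),
    kappa_exp  = list(type = "lognormal", mean = log(5), sd = 1),
    tau        = list(type = "lognormal", mean = 0,      sd = 1),
    psi_safe   = list(type = "halfnormal", sd = 2),
    psi_risky  = list(type = "halfnormal", sd = 2),
    psi        = list(type = "halfnormal", sd = 2)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults)) {
      rs_abort(paste0("unknown prior entry '", nm, "'."), "rs_config_error")
    }
    defaults[[nm]] <- modifyList(defaults[[nm]], overrides[[nm]])
  }
  bad <- vapply(defaults, function(x) !is.finite(x$sd) || x$sd <= 0, logical(1))
  if (any(bad)) rs_abort("prior SDs must be finite and positive.", "rs_config_error")
  structure(defaults, class = "rs_priors")
}

# log prior density of a transformed (log-scale) parameter vector
# theta is named by the variant's free parameters; all entries are logs of
# the natural parameters
log_prior <- function(theta, priors = prior_config()) {
  lp <- 0
  for (nm in names(theta)) {
    pr <- priors[[nm]]
    if (is.null(pr)) rs_abort(paste0("no prior for '", nm, "'."), "rs_config_error")
    if (pr$type == "lognormal") {
      lp <- lp + dnorm(theta[[nm]], pr$mean, pr$sd, log = TRUE)
    } else {
      # half-Normal on the natural scale + log-Jacobian of exp()
      lp <- lp + log(2) + dnorm(exp(theta[[nm]]), 0, pr$sd, log = TRUE) + theta[[nm]]
    }
  }
  lp
}

# transformed-scale mean used to centre optimizer starts / chain inits
prior_start <- function(free, priors = prior_config()) {
  vapply(free, function(nm) {
    pr <- priors[[nm]]
    if (pr$type == "lognormal") pr$mean else log(pr$sd / 2)
  }, numeric(1))
}

# map a transformed free vector to the natural-scale parameter list the
# likelihood consumes
theta_to_params <- function(theta, variant) {
  as.list(setNames(exp(unname(theta)), names(theta)))
}
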