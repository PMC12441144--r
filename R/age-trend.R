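#' Age-trend regression of model parameters
#'
#' Regresses per-subject parameter values on standardized linear and
#' quadratic age polynomials (mean 0, SD 0.5, the convention used for all
#' continuous covariates), one least-squares fit per parameter.  Positive
#' parameters are regressed on the log scale by default, matching the
#' scale on which the generative age-trend model is linear.
#'
#' @param data A tibble with an `age` column and one column per parameter
#'   (e.g. [simulate_population()] output, or [tidy()] estimates pivoted
#'   wide).
#' @param params Character vector of parameter columns to analyse; defaults
#'   to the model parameters present in `data`.
#' @param log_scale Regress `log(parameter)` (default `TRUE`).
#' @return A tibble of class `rs_age_trend`: `parameter`, `term`
#'   (`"age_lin"`/`"age_quad"`), `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @examples
#' pop <- simulate_population(40, seed = 2)
#' fit_age_trend(pop, params = c("kappa_exp", "tau"))
#' @export
fit_age_trend <- function(data, params = NULL, log_scale = TRUE) {
  if (nrow(data) < 3) {
    rs_abort("age-trend regression needs at least 3 subjects.", "rs_rank_error")
  }
  if (length(unique(data$age)) < 3) {
    rs_abort("ages are (nearly) constant; polynomial design is rank-deficient.",
             "rs_rank_error")
  }
  params <- params %||% intersect(
    c("rho", "kappa_desc", "kappa_exp", "psi_safe", "psi_risky", "psi", "tau"),
    names(data)
  )
  if (length(params) == 0) rs_abort("no parameter columns found.", "rs_config_error")
  age_lin <- standardize_half(data$age)
  age_quad <- standardize_half((data$age - mean(data$age))^2)
  out <- purrr::map_dfr(params, function(nm) {
    y <- data[[nm]]
    if (log_scale) {
      if (any(y <= 0)) rs_abort(paste0("non-positive values in '", nm,
                                       "' cannot be log-transformed."),
                                "rs_domain_error")
      y <- log(y)
    }
    fit <- lm(y ~ age_lin + age_quad)
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    purrr::map_dfr(c("age_lin", "age_quad"), function(term) {
      tibble(
        parameter = nm, term = term,
        estimate = sm[term, "Estimate"],
        std_error = sm[term, "Std. Error"],
        statistic = sm[term, "t value"],
        p_value = sm[term, "Pr(>|t|)"],
        conf_low = ci[term, 1], conf_high = ci[term, 2]
      )
    })
  })
  class(out) <- c("rs_age_trend", class(out))
  out
}
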