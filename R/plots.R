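# ggplot2 displays for the main result types

#' Plot risky-choice proportions by age bin, condition and advice
#'
#' @param summary Output of [summarize_behaviour()].
#' @return A ggplot object.
#' @export
plot_behaviour <- function(summary) {
  ggplot(summary, aes(x = .data$age_bin, y = .data$prop_risky,
                      colour = .data$condition, group = .data$condition)) +
    geom_pointrange(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                    position = position_dodge(width = 0.3)) +
    geom_line(position = position_dodge(width = 0.3)) +
    facet_wrap(~.data$social) +
    labs(x = "age bin (years)", y = "proportion of risky choices",
         colour = "condition") +
    theme_minimal()
}

#' Plot susceptibility to social influence by age
#'
#' @param susc Output of [susceptibility()].
#' @param subjects Subject tibble with `subject_id` and `age`.
#' @return A ggplot object.
#' @export
plot_susceptibility <- function(susc, subjects) {
  dat <- susc %>% left_join(subjects %>% select("subject_id", "age"),
                            by = "subject_id")
  ggplot(dat, aes(x = .data$age, y = .data$signed_shift,
                  colour = .data$condition, linetype = .data$advice)) +
    geom_point(alpha = 0.4) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    geom_hline(yintercept = 0, linetype = 3) +
    labs(x = "age (years)", y = "mean belief shift p' - p") +
    theme_minimal()
}

#' Plot model-parameter age trends
#'
#' Boxplots of per-subject parameter values by age bin, one facet per
#' parameter on a log y-scale.
#'
#' @param data Subject tibble with `age` and parameter columns
#'   (true values or estimates).
#' @param params Parameter columns to show.
#' @param age_bins Break points for age bins.
#' @return A ggplot object.
#' @export
plot_age_trends <- function(data,
                            params = c("kappa_desc", "kappa_exp", "psi_safe",
                                       "psi_risky", "rho", "tau"),
                            age_bins = c(10, 13, 17, 21, 26)) {
  params <- intersect(params, names(data))
  dat <- data %>%
    mutate(age_bin = cut(.data$age, age_bins, include.lowest = TRUE)) %>%
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "value")
  ggplot(dat, aes(x = .data$age_bin, y = .data$value)) +
    geom_boxplot(outlier.alpha = 0.3) +
    facet_wrap(~.data$parameter, scales = "free_y") +
    scale_y_log10() +
    labs(x = "age bin (years)", y = "parameter value (log scale)") +
    theme_minimal()
}

#' @export
autoplot.rs_compare <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$variant, .data$elpd_loo),
                     y = .data$elpd_loo)) +
    geom_pointrange(aes(ymin = .data$elpd_loo - .data$se_elpd,
                        ymax = .data$elpd_loo + .data$se_elpd)) +
    coord_flip() +
    labs(x = NULL, y = "elpd (leave-one-trial-out)") +
    theme_minimal()
}

#' @export
autoplot.rs_recovery <- function(object, ...) {
  tab <- object %>% count(.data$generating, .data$winner)
  ggplot(tab, aes(x = .data$winner, y = .data$generating, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n), colour = "white") +
    labs(x = "winning variant", y = "generating variant", fill = "reps") +
    theme_minimal()
}

#' @export
autoplot.rs_age_trend <- function(object, ...) {
  ggplot(object, aes(x = .data$term, y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$conf_low, ymax = .data$conf_high)) +
    geom_hline(yintercept = 0, linetype = 3) +
    facet_wrap(~.data$parameter, scales = "free_y") +
    labs(x = NULL, y = "standardized age-polynomial coefficient") +
    theme_minimal()
}
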