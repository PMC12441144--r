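#' Susceptibility to social influence
#'
#' For every social trial, computes the prior belief mean `p` and the
#' post-advice mean `p'` at a subject's parameter values and aggregates
#' the shift by subject, condition and advice type: `mean_abs_shift` is
#' the mean `|p' - p|` (a value of 0.2 means the subject acted as if the
#' advised jar were 20 percentage points more likely to pay out) and
#' `signed_shift` the mean `p' - p` (positive under risky advice, negative
#' under safe advice whenever the sensitivities are non-negative).
#'
#' @param params_df Per-subject parameters: a tibble with `subject_id`,
#'   `kappa_desc`, `kappa_exp`, `psi_safe`, `psi_risky` columns — either
#'   true generative parameters ([simulate_population()]) or estimates
#'   (e.g. `tidy(fit)` pivoted wide).  A fit object (`rs_map_fits`,
#'   `rs_hier_fit`) is also accepted.
#' @param choices Choice tibble containing the social trials.
#' @return A tibble with one row per subject x condition x advice:
#'   `subject_id`, `condition`, `advice`, `n_trials`, `mean_abs_shift`,
#'   `signed_shift`.
#' @examples
#' pop <- simulate_population(4, seed = 1)
#' sim <- simulate_study(pop, build_design(seed = 1), seed = 1)
#' susceptibility(pop, sim$choices)
#' @export
susceptibility <- function(params_df, choices) {
  if (inherits(params_df, c("rs_map_fits", "rs_hier_fit", "rs_mcmc_fit"))) {
    params_df <- tidy(params_df) %>%
      select("subject_id", "parameter", "estimate") %>%
      tidyr::pivot_wider(names_from = "parameter", values_from = "estimate")
  }
  need <- c("subject_id", "kappa_desc", "kappa_exp")
  if (!all(need %in% names(params_df))) {
    rs_abort("params_df must provide subject_id and kappa estimates.",
             "rs_lookup_error")
  }
  if (!"psi_safe" %in% names(params_df) && "psi" %in% names(params_df)) {
    params_df <- params_df %>%
      mutate(psi_safe = .data$psi, psi_risky = .data$psi)
  }
  social <- choices %>% filter(.data$social %in% c("safe", "risky"))
  missing <- setdiff(unique(social$subject_id), params_df$subject_id)
  if (length(missing) > 0) {
    rs_abort(paste0("no parameters for subject(s): ",
                    paste(missing, collapse = ", ")), "rs_lookup_error")
  }
  social %>%
    left_join(params_df %>%
                select("subject_id", "kappa_desc", "kappa_exp",
                       "psi_safe", "psi_risky"),
              by = "subject_id") %>%
    mutate(
      kappa = ifelse(.data$condition == "experience", .data$kappa_exp, .data$kappa_desc),
      p_prior = .data$p_win,
      p_post = social_update(
        prior_belief(.data$p_win, .data$kappa),
        .data$social, .data$psi_safe, .data$psi_risky
      ),
      shift = .data$p_post - .data$p_prior
    ) %>%
    group_by(.data$subject_id, .data$condition, advice = .data$social) %>%
    summarise(
      n_trials = n(),
      mean_abs_shift = mean(abs(.data$shift)),
      signed_shift = mean(.data$shift),
      .groups = "drop"
    )
}

#' Descriptive behaviour summary with bootstrap intervals
#'
#' Risky-choice proportions by age bin, condition and social information.
#' Proportions are averages of per-subject means (respecting the
#' repeated-measures structure) and the 95% intervals come from
#' resampling subjects with replacement.  Empty cells are reported with
#' `NA` proportions rather than dropped.
#'
#' @param choices Choice tibble.
#' @param subjects Subject tibble with `subject_id` and `age`.
#' @param age_bins Break points for age bins.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A tibble: `age_bin`, `condition`, `social`, `n_subjects`,
#'   `prop_risky`, `conf_low`, `conf_high`.
#' @export
summarize_behaviour <- function(choices, subjects,
                                age_bins = c(10, 13, 17, 21, 26),
                                n_boot = 1000, seed = 1) {
  if (nrow(choices) == 0) rs_abort("empty dataset.", "rs_input_error")
  dat <- choices %>%
    left_join(subjects %>% select("subject_id", "age"), by = "subject_id") %>%
    mutate(age_bin = as.character(cut(.data$age, age_bins, include.lowest = TRUE)))
  per_subject <- dat %>%
    group_by(.data$subject_id, .data$age_bin, .data$condition, .data$social) %>%
    summarise(prop = mean(.data$choice), .groups = "drop")
  cells <- tidyr::expand_grid(
    age_bin = unique(per_subject$age_bin),
    condition = unique(per_subject$condition),
    social = unique(per_subject$social)
  )
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- unique(per_subject$subject_id)
  boot_reps <- replicate(n_boot, {
    take <- sample(ids, length(ids), replace = TRUE)
    per_subject %>%
      dplyr::inner_join(tibble(subject_id = take), by = "subject_id",
                        relationship = "many-to-many") %>%
      group_by(.data$age_bin, .data$condition, .data$social) %>%
      summarise(prop = mean(.data$prop), .groups = "drop")
  }, simplify = FALSE)
  boot <- bind_rows(boot_reps) %>%
    group_by(.data$age_bin, .data$condition, .data$social) %>%
    summarise(conf_low = unname(quantile(.data$prop, 0.025)),
              conf_high = unname(quantile(.data$prop, 0.975)),
              .groups = "drop")
  point <- per_subject %>%
    group_by(.data$age_bin, .data$condition, .data$social) %>%
    summarise(n_subjects = dplyr::n_distinct(.data$subject_id),
              prop_risky = mean(.data$prop), .groups = "drop")
  cells %>%
    left_join(point, by = c("age_bin", "condition", "social")) %>%
    left_join(boot, by = c("age_bin", "condition", "social")) %>%
    mutate(n_subjects = tidyr::replace_na(.data$n_subjects, 0L)) %>%
    arrange(.data$age_bin, .data$condition, .data$social)
}
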