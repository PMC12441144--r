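#' Simulate one subject's choices over a design
#'
#' Forward-simulates the belief-updating model: per trial the choice
#' probability is computed from the subject's parameters under the given
#' variant and a Bernoulli choice is drawn; realized points are drawn from
#' the chosen jar (the risky jar pays `value_risky` with probability
#' `p_win`, the safe jar always pays `safe_value`).
#'
#' @param design Trial tibble from [build_design()] with all `social`
#'   placeholders resolved (no `NA`).
#' @param params Named list/vector of the subject's true parameters.
#' @param variant Generating model variant (default `"m2"`).
#' @param seed Integer seed.
#' @param subject_id Identifier copied into the output.
#' @return A tibble of choice records: the design columns plus `subject_id`,
#'   `cp`, `choice` (1 = risky), `points`.
#' @export
simulate_choices <- function(design, params, variant = "m2", seed = 1,
                             subject_id = "S001") {
  if (anyNA(design$social)) {
    rs_abort("design has unresolved social placeholders; fill advisor choices first.",
             "rs_state_error")
  }
  cp <- choice_prob_trials(design, params, variant)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  choice <- rbinom(nrow(design), 1, cp)
  win <- rbinom(nrow(design), 1, design$p_win)
  design %>%
    mutate(
      subject_id = subject_id,
      cp = cp,
      choice = choice,
      points = ifelse(choice == 1, win * .data$value_risky, .data$safe_value)
    ) %>%
    select("subject_id", "trial_id", "block", "condition", "social",
           "value_risky", "p_win", "safe_value", "sample_sequence",
           "cp", "choice", "points")
}

#' Simulate a pool of risk-prone advisors
#'
#' Advisors are agents with an elevated utility exponent and a lowered
#' temperature relative to a neutral agent, simulated over the full design
#' while ignoring social information (their sessions had none).  Their
#' per-trial choices supply the safe/risky social labels shown to matched
#' participants.
#'
#' @param n_advisors Pool size.
#' @param design Trial tibble from [build_design()].
#' @param seed Integer seed.
#' @param rho,tau,kappa_desc,kappa_exp Advisor parameter centres; small
#'   log-Normal jitter is applied across the pool.
#' @return A tibble with one row per advisor x trial: `advisor_id`,
#'   `trial_id`, `block`, `choice`, plus an attribute-free `first_half_risky`
#'   count column repeated per advisor.
#' @export
build_advisor_pool <- function(n_advisors = 80, design = build_design(), seed = 1,
                               rho = 1.1, tau = 4,
                               kappa_desc = 4, kappa_exp = 3) {
  if (n_advisors < 1) rs_abort("`n_advisors` must be at least 1.", "rs_config_error")
  solo_design <- design %>% mutate(social = "none")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  pool <- purrr::map_dfr(seq_len(n_advisors), function(a) {
    set.seed(seed + 7919L * a)
    pars <- list(
      rho = rho * exp(rnorm(1, 0, 0.12)),
      kappa_desc = kappa_desc, kappa_exp = kappa_exp,
      psi_safe = 0, psi_risky = 0,
      tau = tau * exp(rnorm(1, 0, 0.40))
    )
    simulate_choices(solo_design, pars, variant = "m2",
                     seed = seed + 7919L * a + 1L,
                     subject_id = sprintf("A%03d", a)) %>%
      rename(advisor_id = "subject_id") %>%
      select("advisor_id", "trial_id", "block", "condition", "value_risky",
             "p_win", "choice")
  })
  pool %>%
    group_by(.data$advisor_id) %>%
    mutate(first_half_risky = sum(.data$choice[.data$block == "solo"])) %>%
    ungroup()
}

#' Match a participant to a risk-prone advisor
#'
#' Selects the advisor whose first-half risky-choice count exceeds the
#' participant's first-half count by exactly `target_excess` (default 15,
#' i.e. about 20% of 72 solo trials).  When no advisor matches, the excess
#' is relaxed one integer at a time (15, 14, 13, ...) until a match is
#' found; ties are broken by lowest advisor id.  If no advisor matches at
#' any non-negative excess a matching error is raised rather than relaxing
#' further.
#'
#' @param participant_risky The participant's first-half risky-choice count.
#' @param pool Advisor pool from [build_advisor_pool()].
#' @param target_excess Desired excess in risky choices (default 15).
#' @return A list with `advisor_id` and the `excess` actually achieved.
#' @export
match_advisor <- function(participant_risky, pool, target_excess = 15) {
  if (nrow(pool) == 0) rs_abort("advisor pool is empty.", "rs_match_error")
  if (target_excess < 0) rs_abort("`target_excess` must be non-negative.", "rs_config_error")
  counts <- pool %>%
    dplyr::distinct(.data$advisor_id, .data$first_half_risky) %>%
    arrange(.data$advisor_id)
  for (excess in seq(target_excess, 0)) {
    hit <- counts %>% filter(.data$first_half_risky == participant_risky + excess)
    if (nrow(hit) > 0) {
      return(list(advisor_id = hit$advisor_id[1], excess = excess))
    }
  }
  rs_abort(
    paste0("no advisor in the pool matches a first-half count of ",
           participant_risky, " at any excess between ", target_excess, " and 0."),
    "rs_match_error"
  )
}

#' Simulate a full synthetic study
#'
#' End-to-end driver reproducing the experimental pipeline: build the
#' design, simulate an advisor pool, then for every subject (i) simulate
#' the solo first half, (ii) match an advisor on first-half risky counts,
#' (iii) label each social-half trial with the matched advisor's choice on
#' that same trial (risky choice -> risky advice), and (iv) simulate the
#' social half.
#'
#' @param subjects Population tibble from [simulate_population()].
#' @param design Trial tibble from [build_design()].
#' @param pool Advisor pool; defaults to [build_advisor_pool()] on `design`.
#' @param variant Generating variant for the participants.
#' @param seed Integer master seed; per-subject streams are derived from it
#'   by fixed offsets.
#' @param target_excess Advisor-matching criterion (default 15).
#' @return A list with `choices` (one row per subject x trial, including
#'   the generative `cp`) and `matches` (per-subject advisor id and
#'   achieved excess).
#' @examples
#' pop <- simulate_population(3, seed = 1)
#' des <- build_design(seed = 1)
#' sim <- simulate_study(pop, des, seed = 1)
#' @export
simulate_study <- function(subjects, design = build_design(),
                           pool = NULL, variant = "m2", seed = 1,
                           target_excess = 15) {
  if (is.null(pool)) pool <- build_advisor_pool(design = design, seed = seed + 500L)
  par_cols <- c("rho", "kappa_desc", "kappa_exp", "psi_safe", "psi_risky", "tau")
  res <- purrr::map(seq_len(nrow(subjects)), function(i) {
    sub <- subjects[i, ]
    pars <- as.list(sub[par_cols])
    sseed <- (seed + 104729L * i) %% .Machine$integer.max
    solo <- simulate_choices(design %>% filter(.data$block == "solo"),
                             pars, variant, seed = sseed,
                             subject_id = sub$subject_id)
    m <- match_advisor(sum(solo$choice), pool, target_excess)
    advisor <- pool %>%
      filter(.data$advisor_id == m$advisor_id, .data$block == "social")
    social_half <- design %>%
      filter(.data$block == "social") %>%
      select(-"social") %>%
      left_join(advisor %>%
                  mutate(social = ifelse(.data$choice == 1, "risky", "safe")) %>%
                  select("trial_id", "social"),
                by = "trial_id")
    soc <- simulate_choices(social_half, pars, variant, seed = sseed + 1L,
                            subject_id = sub$subject_id)
    list(
      choices = bind_rows(solo, soc) %>% arrange(.data$trial_id),
      match = tibble(subject_id = sub$subject_id,
                     advisor_id = m$advisor_id, excess = m$excess)
    )
  })
  list(
    choices = purrr::map_dfr(res, "choices"),
    matches = purrr::map_dfr(res, "match")
  )
}

#' Write / read choice records as CSV
#'
#' The schema written here is exactly the schema the fitting functions
#' consume, so simulated datasets round-trip through disk.
#'
#' @param choices Choice tibble from [simulate_choices()]/[simulate_study()].
#' @param path File path.
#' @return `read_choices()` returns the choice tibble.
#' @export
write_choices <- function(choices, path) {
  readr::write_csv(choices, path)
  invisible(path)
}

#' @rdname write_choices
#' @export
read_choices <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    trial_id = readr::col_integer(),
    block = readr::col_character(),
    condition = readr::col_character(),
    social = readr::col_character(),
    value_risky = readr::col_double(),
    p_win = readr::col_double(),
    safe_value = readr::col_double(),
    sample_sequence = readr::col_character(),
    cp = readr::col_double(),
    choice = readr::col_integer(),
    points = readr::col_double()
  )) %>%
    mutate(sample_sequence = tidyr::replace_na(.data$sample_sequence, ""))
}
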