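#' Configuration for the lottery task design
#'
#' Defaults reproduce the marble task: risky values of 8, 20 and 50 points,
#' win probabilities from 0.125 to 0.75, eight repetitions of every
#' value-by-probability combination (144 trials), a safe jar always worth 5
#' points, and nine predetermined marble samples on experience trials.
#' Social information is absent in the first (solo) half and attached to
#' every trial of the second (social) half.
#'
#' @param values Risky point values.
#' @param probabilities Win probabilities, all strictly inside (0, 1).
#' @param repetitions Repetitions of each value-by-probability cell;
#'   must be a positive multiple that allows an even solo/social split when
#'   greater than 1.
#' @param safe_value Certain payoff of the safe jar, in points.
#' @param n_samples Number of marbles shown on an experience trial.
#' @param bonus_rate Euro paid per point at the end of the session.
#' @return A list of class `rs_design_config`.
#' @export
design_config <- function(values = c(8, 20, 50),
                          probabilities = c(0.125, 0.25, 0.375, 0.5, 0.625, 0.75),
                          repetitions = 8,
                          safe_value = 5,
                          n_samples = 9,
                          bonus_rate = 0.008) {
  if (any(probabilities <= 0 | probabilities >= 1)) {
    rs_abort("probabilities must lie strictly inside (0, 1).", "rs_config_error")
  }
  if (repetitions < 1 || repetitions != round(repetitions)) {
    rs_abort("`repetitions` must be a positive integer.", "rs_config_error")
  }
  if (n_samples < 1) rs_abort("`n_samples` must be at least 1.", "rs_config_error")
  structure(
    list(values = values, probabilities = probabilities,
         repetitions = as.integer(repetitions), safe_value = safe_value,
         n_samples = as.integer(n_samples), bonus_rate = bonus_rate),
    class = "rs_design_config"
  )
}

# representative blue-marble count for one repetition of a cell:
# round-half-to-even of n*p, except exact .5 ties alternate floor/ceil
# across repetitions so the cell mean equals n*p
representative_blue <- function(p_win, n_samples, repetition_index) {
  x <- n_samples * p_win
  if (abs(x - floor(x) - 0.5) < 1e-12) {
    if (repetition_index %% 2 == 0) floor(x) else ceiling(x)
  } else {
    round(x) # round() is round-half-to-even in R, but ties are handled above
  }
}

#' Predetermined marble sample sequence for an experience trial
#'
#' Builds the ordered sequence of blue ("B") and red ("R") marbles shown
#' before an experience decision.  The number of blue marbles is the nearest
#' integer to `n_samples * p_win` (ties alternate floor/ceiling across
#' repetitions so that repeated presentations average out exactly), making
#' the samples as representative of the generative probability as possible.
#' Blues are spread evenly through the sequence and the whole sequence is
#' rotated by the repetition index, so the order is a deterministic function
#' of `(p_win, n_samples, repetition_index)`.
#'
#' @param p_win Win probability, strictly inside (0, 1).
#' @param n_samples Sequence length (default 9).
#' @param repetition_index 0-based repetition counter within the
#'   value-by-probability cell.
#' @return Character vector of `"B"`/`"R"` of length `n_samples`.
#' @examples
#' make_sample_sequence(0.75, 9, 0)
#' @export
make_sample_sequence <- function(p_win, n_samples = 9, repetition_index = 0) {
  if (p_win <= 0 || p_win >= 1) {
    rs_abort("`p_win` must lie strictly inside (0, 1).", "rs_domain_error")
  }
  if (n_samples < 1) rs_abort("`n_samples` must be at least 1.", "rs_domain_error")
  b <- representative_blue(p_win, n_samples, repetition_index)
  i <- seq_len(n_samples)
  # Bresenham-style even spread of b blues among n positions
  blue_at <- floor(i * b / n_samples) > floor((i - 1) * b / n_samples)
  seq0 <- ifelse(blue_at, "B", "R")
  rot <- repetition_index %% n_samples
  if (rot > 0) seq0 <- c(seq0[-seq_len(rot)], seq0[seq_len(rot)]) else seq0
}

#' Generate the full randomised trial list
#'
#' Crosses risky values, win probabilities and the description/experience
#' conditions, splits repetitions evenly between a first (solo) half with no
#' social information and a second (social) half, randomises trial order
#' within each half, and attaches predetermined sample sequences to
#' experience trials.  Social trials carry `social = NA` placeholders until
#' an advisor's choices are filled in (see [simulate_study()]).
#'
#' @param config An [design_config()] object.
#' @param seed Integer seed controlling the trial order.
#' @return A tibble with one row per trial: `trial_id` (0-based), `block`
#'   (`"solo"`/`"social"`), `condition`, `social`, `value_risky`, `p_win`,
#'   `safe_value`, `sample_sequence` (e.g. `"BBRBBBRBB"`, `""` on
#'   description trials).
#' @examples
#' design <- build_design(design_config(), seed = 1)
#' nrow(design)
#' @export
build_design <- function(config = design_config(), seed = 1) {
  if (!inherits(config, "rs_design_config")) config <- do.call(design_config, config)
  cells <- tidyr::expand_grid(
    value_risky = config$values,
    p_win = config$probabilities,
    rep_global = seq_len(config$repetitions) - 1L
  )
  # repetitions alternate condition and half so each (value, p, condition)
  # cell is balanced across the solo and social halves
  cells <- cells %>%
    mutate(
      condition = ifelse(.data$rep_global %% 2 == 0, "description", "experience"),
      block = ifelse(.data$rep_global %/% 2 %% 2 == 0, "solo", "social")
    ) %>%
    group_by(.data$value_risky, .data$p_win, .data$condition) %>%
    mutate(rep_in_cell = row_number() - 1L) %>%
    ungroup()

  cells$sample_sequence <- purrr::pmap_chr(
    cells[c("p_win", "condition", "rep_in_cell")],
    function(p_win, condition, rep_in_cell) {
      if (condition == "experience") {
        paste(make_sample_sequence(p_win, config$n_samples, rep_in_cell), collapse = "")
      } else ""
    }
  )

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  solo <- cells %>% filter(.data$block == "solo") %>% slice(sample(n()))
  soc <- cells %>% filter(.data$block == "social") %>% slice(sample(n()))
  design <- bind_rows(solo, soc) %>%
    mutate(
      trial_id = row_number() - 1L,
      social = ifelse(.data$block == "solo", "none", NA_character_),
      safe_value = config$safe_value
    ) %>%
    select("trial_id", "block", "condition", "social", "value_risky",
           "p_win", "safe_value", "sample_sequence")
  design
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Session bonus implied by collected points
#'
#' @param points Total points collected.
#' @param rate Euro per point (default taken from [design_config()]).
#' @return Bonus payment in euro.
#' @export
bonus_payment <- function(points, rate = design_config()$bonus_rate) {
  points * rate
}

#' Write / read a design table as CSV
#'
#' The sample sequence is serialised as a string of `B`/`R` characters so
#' the file round-trips field-for-field.
#'
#' @param design A design tibble from [build_design()].
#' @param path File path.
#' @return `read_design()` returns the design tibble.
#' @export
write_design <- function(design, path) {
  readr::write_csv(design, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trial_id = readr::col_integer(),
    block = readr::col_character(),
    condition = readr::col_character(),
    social = readr::col_character(),
    value_risky = readr::col_double(),
    p_win = readr::col_double(),
    safe_value = readr::col_double(),
    sample_sequence = readr::col_character()
  )) %>%
    mutate(sample_sequence = tidyr::replace_na(.data$sample_sequence, ""))
}
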