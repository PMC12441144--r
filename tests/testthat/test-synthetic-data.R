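test_that("population standardization meets the mean-0 SD-0.5 convention", {
  pop <- simulate_population(166, seed = 4)
  expect_lt(abs(mean(pop$age_lin)), 1e-8)
  expect_lt(abs(sd(pop$age_lin) - 0.5), 1e-8)
  expect_lt(abs(mean(pop$age_quad)), 1e-8)
  expect_lt(abs(sd(pop$age_quad) - 0.5), 1e-8)
  expect_true(all(pop$age >= 10 & pop$age <= 26))
  expect_true(all(pop$group %in% c("G1", "G2", "G3")))
})

test_that("default age trends carry the expected signs at n = 166", {
  pop <- simulate_population(166, seed = 5)
  expect_gt(cor(pop$age, log(pop$kappa_exp)), 0)
  expect_lt(cor(pop$age, log(pop$psi_safe)), 0)
  expect_lt(cor(pop$age, log(pop$psi_risky)), 0)
  expect_lt(cor(pop$age, log(pop$tau)), 0)
  # description-condition uncertainty is age-flat: correlation is small
  expect_lt(abs(cor(pop$age, log(pop$kappa_desc))), 0.25)
})

test_that("zero slopes and dispersion give identical parameters; seeds reproduce", {
  flat <- age_trend_config(params = lapply(
    setNames(nm = c("rho", "kappa_desc", "kappa_exp", "psi_safe", "psi_risky", "tau")),
    function(nm) list(b_lin = 0, b_quad = 0, sd = 0)
  ))
  pop <- simulate_population(10, flat, seed = 6)
  for (p in c("rho", "kappa_exp", "psi_safe", "tau")) {
    expect_equal(length(unique(pop[[p]])), 1)
  }
  expect_identical(simulate_population(20, seed = 7), simulate_population(20, seed = 7))
  expect_error(age_trend_config(params = list(tau = list(sd = -1))),
               class = "rs_config_error")
  expect_error(age_trend_config(params = list(nonsense = list(sd = 1))),
               class = "rs_config_error")
})

test_that("forward simulation respects its deterministic and long-run limits", {
  solo <- fix_design() %>% dplyr::filter(block == "solo")
  # near-zero temperature: every positive-EU-difference trial is chosen risky
  pars <- fix_params(rho = 1.2, tau = 1e-4)
  eus <- expected_utilities(solo, pars, "m2")
  rec <- simulate_choices(solo, pars, "m2", seed = 8)
  expect_equal(rec$choice, as.integer(eus$eu_risk > eus$eu_safe))
  # equal-EV lottery at rho = 1: long-run risky rate is 0.5
  tr <- tibble::tibble(trial_id = seq_len(10000) - 1L, block = "solo",
                       condition = "description", social = "none",
                       value_risky = 8, p_win = 0.625, safe_value = 5,
                       sample_sequence = "")
  rec2 <- simulate_choices(tr, fix_params(rho = 1), "m2", seed = 9)
  expect_equal(mean(rec2$choice), 0.5, tolerance = 0.015)
  # realized points come from the chosen jar
  expect_true(all(rec2$points %in% c(0, 5, 8)))
  expect_true(all(rec2$points[rec2$choice == 0] == 5))
})

test_that("risky advice raises risky rates for socially sensitive agents", {
  design <- fix_design() %>%
    dplyr::mutate(social = dplyr::coalesce(social,
                                           rep_len(c("safe", "risky"), dplyr::n())))
  pars <- fix_params(psi_risky = 3, psi_safe = 3, kappa_desc = 2, kappa_exp = 2)
  rec <- simulate_choices(design, pars, "m2", seed = 10)
  rate <- function(s) mean(rec$choice[rec$social == s])
  expect_gt(rate("risky"), rate("none"))
  expect_lt(rate("safe"), rate("none"))
})

test_that("unresolved social placeholders are a state error", {
  expect_error(simulate_choices(fix_design(), fix_params(), seed = 1),
               class = "rs_state_error")
})

test_that("advisor matching applies the +15 criterion with integer relaxation", {
  pool <- tibble::tibble(
    advisor_id = c("A001", "A002", "A003"),
    first_half_risky = c(45, 42, 45),
    block = "solo", trial_id = 0L, choice = 1L
  )
  # exact +15 available
  m <- match_advisor(30, pool, 15)
  expect_equal(m$advisor_id, "A001") # tie with A003 broken by lowest id
  expect_equal(m$excess, 15)
  # relaxation 15 -> 12
  pool2 <- pool %>% dplyr::filter(advisor_id == "A002")
  m2 <- match_advisor(30, pool2, 15)
  expect_equal(m2$excess, 12)
  expect_equal(m2$advisor_id, "A002")
  # exhausted pool
  expect_error(match_advisor(50, pool2, 15), class = "rs_match_error")
  expect_error(match_advisor(30, pool[0, ], 15), class = "rs_match_error")
})

test_that("risk-prone advisor pools make more risky choices than neutral ones", {
  des <- fix_small_design()
  prone <- build_advisor_pool(12, des, seed = 11, rho = 1.2)
  neutral <- build_advisor_pool(12, des, seed = 11, rho = 1.0)
  expect_gt(mean(prone$choice), mean(neutral$choice))
  expect_identical(build_advisor_pool(5, des, seed = 12),
                   build_advisor_pool(5, des, seed = 12))
  expect_error(build_advisor_pool(0, des), class = "rs_config_error")
})

test_that("the simulated study resolves social labels from the matched advisor", {
  study <- fix_study()
  ch <- study$choices
  expect_false(anyNA(ch$social))
  expect_true(all(ch$social[ch$block == "solo"] == "none"))
  expect_true(all(ch$social[ch$block == "social"] %in% c("safe", "risky")))
  expect_equal(nrow(ch), nrow(study$pop) * 144)
  expect_true(all(study$matches$excess >= 0 & study$matches$excess <= 15))
})

test_that("choice records round-trip through CSV in the schema inference reads", {
  study <- fix_study()
  path <- withr::local_tempfile(fileext = ".csv")
  write_choices(study$choices, path)
  back <- read_choices(path)
  expect_equal(as.data.frame(back), as.data.frame(study$choices),
               tolerance = 1e-12)
})
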