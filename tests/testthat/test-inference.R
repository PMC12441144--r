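test_that("MAP recovery of the utility-only model is unbiased at scale", {
  # oracle established by simulation: 50 replicate subjects generated from
  # m0 with rho = 1, tau = 2 over the 144-trial design
  des <- build_design(seed = 77) %>%
    dplyr::mutate(social = tidyr::replace_na(social, "none"))
  rhos <- vapply(1:50, function(i) {
    ch <- simulate_choices(des, list(rho = 1, tau = 2), "m0", seed = 1000 + i)
    f <- fit_subject_map(ch, "m0", seed = i, laplace_draws = 0)
    exp(f$theta[["rho"]])
  }, numeric(1))
  expect_lt(abs(median(rhos) - 1), 0.15)
})

test_that("degenerate all-identical choices are flagged, not silently returned", {
  des <- fix_small_design() %>% dplyr::mutate(social = "none")
  ch <- simulate_choices(des, fix_params(), "m0", seed = 2)
  ch$choice <- 1L
  f <- fit_subject_map(ch, "m0", seed = 3)
  expect_true(f$degenerate_data)
  expect_true(f$converged)
})

test_that("MAP refits are deterministic given the seed", {
  study <- fix_study()
  ch <- study$choices %>% dplyr::filter(subject_id == "S001")
  f1 <- fit_subject_map(ch, "m2", seed = 42)
  f2 <- fit_subject_map(ch, "m2", seed = 42)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$draws, f2$draws)
})

test_that("hierarchical likelihood equals the core model likelihood", {
  study <- fix_study()
  ch <- study$choices
  ids <- unique(ch$subject_id)
  theta <- matrix(log(c(0.9, 3, 2, 1.5, 1.2, 1)), length(ids), 6, byrow = TRUE)
  ch_sorted <- ch %>% dplyr::arrange(match(subject_id, ids), trial_id)
  prep <- riskysocial:::prep_trials(ch_sorted, "m2")
  s_of_row <- match(ch_sorted$subject_id, ids)
  nat <- exp(theta); colnames(nat) <- riskysocial:::variant_spec("m2")$free
  pars <- riskysocial:::canonical_matrix(nat, "m2", length(ids))
  ll_fast <- riskysocial:::fast_loglik(
    prep, pars$rho[s_of_row], pars$kappa_desc[s_of_row],
    pars$kappa_exp[s_of_row], pars$psi_safe[s_of_row],
    pars$psi_risky[s_of_row], pars$tau[s_of_row])
  ll_core <- trial_loglik(ch_sorted, list(rho = 0.9, kappa_desc = 3,
                                          kappa_exp = 2, psi_safe = 1.5,
                                          psi_risky = 1.2, tau = 1), "m2")
  expect_equal(ll_fast, ll_core, tolerance = 1e-8)
})

test_that("null-effect data give indistinguishable group-level means", {
  flat <- age_trend_config(params = lapply(
    setNames(nm = c("rho", "kappa_desc", "kappa_exp", "psi_safe", "psi_risky", "tau")),
    function(nm) list(b_lin = 0, b_quad = 0)
  ))
  pop <- simulate_population(12, flat, seed = 21)
  sim <- simulate_study(pop, fix_design(21), seed = 21)
  fit <- suppressWarnings(
    fit_hierarchical(sim$choices, pop, "m2s",
                     mcmc_config(chains = 2, iter = 1200, warmup = 600, thin = 3),
                     seed = 21)
  )
  # posterior of (mu_G1 - mu_G3) covers 0 for every parameter
  free <- fit$free
  g1 <- match("G1", fit$groups); g3 <- match("G3", fit$groups)
  for (p in seq_along(free)) {
    d <- as.numeric(fit$mu_draws[, , g1, p] - fit$mu_draws[, , g3, p])
    ci <- quantile(d, c(0.025, 0.975))
    expect_true(ci[1] < 0 && ci[2] > 0)
  }
})

test_that("an under-iterated run triggers a convergence warning", {
  study <- fix_study()
  expect_warning(
    fit_hierarchical(study$choices %>%
                       dplyr::filter(subject_id %in% c("S001", "S002", "S003")),
                     study$pop, "m2",
                     mcmc_config(chains = 2, iter = 60, warmup = 30, thin = 1),
                     seed = 31),
    class = "rs_convergence_warning"
  )
})

test_that("prior-predictive simulation stays inside sane risky-rate bounds", {
  des <- build_design(seed = 77) %>%
    dplyr::mutate(social = tidyr::replace_na(social, "none"))
  set.seed(3)
  rates <- vapply(1:40, function(i) {
    th <- c(rho = rnorm(1, 0, 0.5), kappa_desc = rnorm(1, log(5), 1),
            kappa_exp = rnorm(1, log(5), 1),
            psi_safe = log(abs(rnorm(1, 0, 2)) + 1e-6),
            psi_risky = log(abs(rnorm(1, 0, 2)) + 1e-6),
            tau = rnorm(1, 0, 1))
    ch <- simulate_choices(des, as.list(exp(th)), "m2", seed = 50 + i)
    mean(ch$choice)
  }, numeric(1))
  expect_true(all(rates > 0.05 & rates < 0.95))
  expect_gt(diff(range(rates)), 0.3)
})

test_that("age-trend regression recovers generative slopes and calibrates", {
  pop <- simulate_population(166, seed = 41)
  tr <- fit_age_trend(pop, params = c("kappa_exp", "psi_safe"))
  ke <- tr %>% dplyr::filter(parameter == "kappa_exp", term == "age_lin")
  expect_gt(ke$estimate, 0)
  expect_gt(abs(ke$statistic), 2)
  ps <- tr %>% dplyr::filter(parameter == "psi_safe", term == "age_lin")
  expect_lt(ps$estimate, 0)
  # calibration: a zero-slope parameter is covered by the 95% CI ~95% of runs
  set.seed(42)
  cover <- vapply(1:200, function(i) {
    n <- 60
    age <- runif(n, 10, 26)
    dat <- tibble::tibble(age = age, kappa_desc = exp(rnorm(n, log(3), 0.5)))
    row <- fit_age_trend(dat, "kappa_desc") %>% dplyr::filter(term == "age_lin")
    row$conf_low < 0 && row$conf_high > 0
  }, logical(1))
  expect_gt(mean(cover), 0.89)
  expect_lt(mean(cover), 0.995)
})

test_that("age-trend regression rejects deficient inputs", {
  expect_error(fit_age_trend(tibble::tibble(age = c(10, 20), tau = c(1, 2))),
               class = "rs_rank_error")
  expect_error(
    fit_age_trend(tibble::tibble(age = rep(15, 10), tau = exp(rnorm(10)))),
    class = "rs_rank_error"
  )
})

test_that("mcmc and prior configurations validate", {
  expect_error(mcmc_config(iter = 100, warmup = 200), class = "rs_config_error")
  paper <- mcmc_config(preset = "paper")
  expect_equal(paper$iter, 6000L)
  expect_equal(paper$warmup, 2000L)
  expect_error(prior_config(tau = list(sd = -1)), class = "rs_config_error")
  expect_error(prior_config(bogus = list(sd = 1)), class = "rs_config_error")
})
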