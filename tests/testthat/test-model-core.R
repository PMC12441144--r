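test_that("power utility evaluates and validates its domain", {
  expect_equal(utility(5, 1), 5)
  expect_equal(utility(50, 0.5), 7.0711, tolerance = 1e-4)
  expect_equal(utility(0, 0.7), 0)
  expect_error(utility(-1, 1), class = "rs_domain_error")
  expect_error(utility(5, 0), class = "rs_domain_error")
})

test_that("prior beliefs follow the pseudo-count parameterisation", {
  b <- prior_belief(0.5, 2)
  expect_equal(b$alpha, 1)
  expect_equal(b$beta, 1)
  expect_equal(b$p_prior, 0.5)
  b2 <- prior_belief(0.75, 20)
  expect_equal(b2$alpha, 15)
  expect_equal(b2$beta, 5)
  # mean is invariant to the pseudo-count rate
  expect_equal(prior_belief(0.5, 20)$p_prior, 0.5)
  expect_error(prior_belief(0, 2), class = "rs_domain_error")
  expect_error(prior_belief(0.5, 0), class = "rs_domain_error")
})

test_that("social updates follow weighted Bayesian updating", {
  expect_equal(social_update(prior_belief(0.5, 2), "risky", 1, 1), 2 / 3,
               tolerance = 1e-10)
  # psi of 0 leaves the prior untouched for any advice
  for (soc in c("none", "safe", "risky")) {
    expect_equal(social_update(prior_belief(0.3, 7), soc, 0, 0), 0.3,
                 tolerance = 1e-12)
  }
  # less internal uncertainty (larger kappa) means a smaller shift
  expect_equal(social_update(prior_belief(0.5, 20), "risky", 1, 1), 11 / 21,
               tolerance = 1e-10)
  expect_error(social_update(prior_belief(0.5, 2), "risky", -1, 1),
               class = "rs_domain_error")
})

test_that("update equals the numerically integrated posterior-beta mean", {
  # independent oracle: mean of beta(alpha + psi*SI_risk, beta + psi*SI_safe)
  # by numerical integration
  # E[X] = integral of the upper tail 1 - F(x); bounded smooth integrand,
  # stable even for pseudo-counts below 1
  beta_mean_numeric <- function(a, b) {
    stats::integrate(function(x) stats::pbeta(x, a, b, lower.tail = FALSE),
                     0, 1, rel.tol = 1e-12)$value
  }
  for (p in c(0.125, 0.5, 0.75)) {
    for (kappa in c(0.5, 2, 20)) {
      for (psi in c(0, 0.5, 1, 4)) {
        bel <- prior_belief(p, kappa)
        expect_equal(social_update(bel, "risky", psi, psi),
                     beta_mean_numeric(bel$alpha + psi, bel$beta),
                     tolerance = 1e-10)
        expect_equal(social_update(bel, "safe", psi, psi),
                     beta_mean_numeric(bel$alpha, bel$beta + psi),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("expected utilities compose belief, advice and utility", {
  tr <- tibble::tibble(value_risky = 8, p_win = 0.625, condition = "description",
                       social = "none", safe_value = 5)
  eus <- expected_utilities(tr, fix_params(rho = 1), "m2")
  expect_equal(eus$eu_risk, 5)
  expect_equal(eus$eu_safe, 5)
  tr2 <- tibble::tibble(value_risky = 50, p_win = 0.5, condition = "description",
                        social = "risky", safe_value = 5)
  eus2 <- expected_utilities(tr2, fix_params(rho = 1, kappa_desc = 2,
                                             psi_risky = 1), "m2")
  expect_equal(eus2$eu_risk, 2 / 3 * 50, tolerance = 1e-9)
})

test_that("softmax choice rule behaves as a logistic in the EU difference", {
  expect_equal(choice_probability(5, 5, 1), 0.5)
  expect_equal(choice_probability(6, 5, 1), 0.7311, tolerance = 1e-4)
  expect_equal(choice_probability(6, 5, 1000), 0.5, tolerance = 1e-3)
  expect_true(choice_probability(7, 5, 1) > choice_probability(6, 5, 1))
  expect_error(choice_probability(1, 1, 0), class = "rs_domain_error")
})

test_that("trial log-likelihood is Bernoulli over the choice probability", {
  tr <- fix_small_design() %>%
    dplyr::mutate(social = tidyr::replace_na(social, "none"), choice = 1)
  # equal-EV case: cp = 0.5 exactly
  tr05 <- tibble::tibble(value_risky = 8, p_win = 0.625, condition = "description",
                         social = "none", safe_value = 5,
                         choice = c(1, 0))
  ll <- trial_loglik(tr05, fix_params(rho = 1), "m2")
  expect_equal(ll, rep(log(0.5), 2))
  # 144 trials at cp = 0.5 sum to 144 * ln 0.5
  tr144 <- tr05[rep(1, 144), ]
  expect_equal(sum(trial_loglik(tr144, fix_params(rho = 1), "m2")),
               144 * log(0.5), tolerance = 1e-9)
  expect_error(trial_loglik(dplyr::mutate(tr05, choice = 2), fix_params()),
               class = "rs_domain_error")
})

test_that("variant nesting reproduces the simpler models bitwise", {
  design <- fix_design() %>%
    dplyr::mutate(social = dplyr::coalesce(social,
                                           rep_len(c("safe", "risky"), dplyr::n())))
  p_m0 <- riskysocial:::choice_prob_trials(design, fix_params(), "m0")
  p_m1 <- riskysocial:::choice_prob_trials(
    design, fix_params(kappa_desc = 4, kappa_exp = 2), "m1")
  p_full_psi0 <- riskysocial:::choice_prob_trials(
    design, fix_params(psi_safe = 0, psi_risky = 0), "m2")
  p_full_psi1 <- riskysocial:::choice_prob_trials(
    design, fix_params(kappa_desc = 4, kappa_exp = 2, psi_safe = 1, psi_risky = 1),
    "m2")
  expect_identical(p_full_psi0, p_m0)
  expect_identical(p_full_psi1, p_m1)
  # and the single-psi variant matches the full model with tied weights
  p_m2s <- riskysocial:::choice_prob_trials(
    design, list(rho = 1, kappa_desc = 4, kappa_exp = 2, psi = 1.5, tau = 2), "m2s")
  p_m2tied <- riskysocial:::choice_prob_trials(
    design, fix_params(kappa_desc = 4, kappa_exp = 2, psi_safe = 1.5,
                       psi_risky = 1.5), "m2")
  expect_identical(p_m2s, p_m2tied)
})

test_that("belief shifts shrink with kappa and grow with psi", {
  kappas <- c(0.5, 1, 2, 5, 10, 40)
  shifts <- vapply(kappas, function(k) {
    abs(social_update(prior_belief(0.5, k), "risky", 2, 2) - 0.5)
  }, numeric(1))
  expect_true(all(diff(shifts) < 0))
  psis <- c(0.1, 0.5, 1, 2, 5, 10)
  shifts_psi <- vapply(psis, function(ps) {
    abs(social_update(prior_belief(0.5, 4), "safe", ps, ps) - 0.5)
  }, numeric(1))
  expect_true(all(diff(shifts_psi) > 0))
})

test_that("kappa is not identified from solo trials", {
  solo <- fix_design() %>% dplyr::filter(block == "solo")
  set.seed(1)
  solo$choice <- rbinom(nrow(solo), 1, 0.5)
  ll_at <- function(k) {
    sum(trial_loglik(solo, fix_params(kappa_desc = k, kappa_exp = k), "m2"))
  }
  # likelihood is exactly flat in kappa: numerical gradient is zero
  expect_equal(ll_at(2), ll_at(20), tolerance = 1e-12)
  expect_equal((ll_at(5 + 1e-4) - ll_at(5 - 1e-4)) / 2e-4, 0, tolerance = 1e-8)
})

test_that("fast likelihood path agrees with the tibble path", {
  study <- fix_study()
  ch <- study$choices %>% dplyr::filter(subject_id == "S002")
  pars <- fix_params(kappa_desc = 3, kappa_exp = 1.5, psi_safe = 2,
                     psi_risky = 0.7, tau = 0.9, rho = 0.85)
  prep <- riskysocial:::prep_trials(ch, "m2")
  fast <- riskysocial:::fast_loglik(prep, pars$rho, pars$kappa_desc,
                                    pars$kappa_exp, pars$psi_safe,
                                    pars$psi_risky, pars$tau)
  expect_equal(fast, trial_loglik(ch, pars, "m2"), tolerance = 1e-8)
})

test_that("unknown variants and missing parameters are configuration errors", {
  expect_error(riskysocial:::variant_spec("m9"), class = "rs_config_error")
  expect_error(riskysocial:::canonical_params(list(rho = 1), "m2"),
               class = "rs_config_error")
  expect_equal(nrow(model_variants()), 4)
})
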