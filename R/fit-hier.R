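#' Hierarchical Bayesian fit with age-group hyperpriors
#'
#' Subject-level transformed parameters are drawn from Normal group-level
#' distributions, one per age group and parameter:
#' `theta[s, p] ~ N(mu[g(s), p], sigma[g(s), p])`, with weak hyperpriors
#' `mu ~ N(m0_p, 1.5)` (centred on the [prior_config()] means) and
#' `sigma ~ half-Normal(0, 1)`.  Sampling is Metropolis-within-Gibbs:
#' subject blocks are updated by adaptive random-walk proposals evaluated
#' in a single vectorised likelihood pass over all subjects, group means
#' are updated by their conjugate Gibbs step, and group SDs by a
#' random-walk on the log scale.  Split-chain R-hat is recorded for every
#' sampled quantity and a convergence warning is attached when any exceeds
#' the threshold (default 1.01).
#'
#' @param choices Choice tibble for all subjects (schema of
#'   [simulate_study()]`$choices`).
#' @param subjects Subject tibble with `subject_id` and `group` columns
#'   ([simulate_population()] output works directly).
#' @param variant Model variant id.
#' @param mcmc An [mcmc_config()].
#' @param priors A [prior_config()] (supplies hyperprior centres).
#' @param seed Integer seed.
#' @return An object of class `rs_hier_fit`: posterior draws of group-level
#'   means/SDs and subject parameters, R-hat per quantity, the
#'   draws-by-observations pointwise log-likelihood matrix, per-subject
#'   posterior summaries and metadata.
#' @export
fit_hierarchical <- function(choices, subjects, variant = "m2",
                             mcmc = mcmc_config(), priors = prior_config(),
                             seed = 1) {
  free <- variant_spec(variant)$free
  P <- length(free)
  ids <- unique(choices$subject_id)
  S <- length(ids)
  sub <- subjects %>% filter(.data$subject_id %in% ids)
  if (!all(ids %in% sub$subject_id)) {
    rs_abort("every subject in `choices` needs a `group` in `subjects`.",
             "rs_config_error")
  }
  grp <- sub$group[match(ids, sub$subject_id)]
  groups <- sort(unique(grp))
  G <- length(groups)
  g_of_s <- match(grp, groups)

  choices <- choices %>% arrange(match(.data$subject_id, ids), .data$trial_id)
  prep <- prep_trials(choices, variant)
  s_of_row <- match(choices$subject_id, ids)
  n_obs <- prep$n

  # vectorised subject log-likelihoods for a theta matrix [S x P]
  ll_subjects <- function(theta) {
    nat <- exp(theta)
    colnames(nat) <- free
    pars <- canonical_matrix(nat, variant, S)
    ll <- fast_loglik(prep,
                      pars$rho[s_of_row], pars$kappa_desc[s_of_row],
                      pars$kappa_exp[s_of_row], pars$psi_safe[s_of_row],
                      pars$psi_risky[s_of_row], pars$tau[s_of_row])
    as.numeric(rowsum(ll, s_of_row))
  }
  ll_pointwise <- function(theta) {
    nat <- exp(theta)
    colnames(nat) <- free
    pars <- canonical_matrix(nat, variant, S)
    fast_loglik(prep,
                pars$rho[s_of_row], pars$kappa_desc[s_of_row],
                pars$kappa_exp[s_of_row], pars$psi_safe[s_of_row],
                pars$psi_risky[s_of_row], pars$tau[s_of_row])
  }

  m0 <- prior_start(free, priors)
  s0 <- 1.5
  n_save <- floor((mcmc$iter - mcmc$warmup) / mcmc$thin)
  chains <- mcmc$chains

  mu_draws <- array(NA_real_, c(n_save, chains, G, P))
  sig_draws <- array(NA_real_, c(n_save, chains, G, P))
  theta_draws <- array(NA_real_, c(n_save, chains, S, P))
  pw <- matrix(NA_real_, n_save * chains, n_obs)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (ch in seq_len(chains)) {
    set.seed((seed + 7717L * ch) %% .Machine$integer.max)
    theta <- matrix(rep(m0, each = S), S, P) + matrix(rnorm(S * P, 0, 0.2), S, P)
    mu <- matrix(rep(m0, each = G), G, P) + matrix(rnorm(G * P, 0, 0.2), G, P)
    sigma <- matrix(0.5, G, P)
    ll <- ll_subjects(theta)
    prop_scale <- matrix(0.15, S, P)
    sig_scale <- matrix(0.3, G, P)
    acc <- matrix(0L, S, P); win <- 0
    k <- 0
    for (it in seq_len(mcmc$iter)) {
      # --- subject parameters, one coordinate at a time, vectorised
      # across subjects (accept/reject independently per subject)
      for (p in seq_len(P)) {
        prop <- theta
        prop[, p] <- theta[, p] + rnorm(S) * prop_scale[, p]
        ll_prop <- ll_subjects(prop)
        pr_cur <- dnorm(theta[, p], mu[g_of_s, p], sigma[g_of_s, p], log = TRUE)
        pr_prop <- dnorm(prop[, p], mu[g_of_s, p], sigma[g_of_s, p], log = TRUE)
        take <- log(runif(S)) < (ll_prop + pr_prop - ll - pr_cur)
        theta[take, p] <- prop[take, p]
        ll[take] <- ll_prop[take]
        acc[, p] <- acc[, p] + take
      }
      win <- win + 1
      if (it <= mcmc$warmup && win == 50) {
        prop_scale <- prop_scale * exp(acc / win - 0.44)
        acc[] <- 0L; win <- 0
      }
      # --- group means: conjugate Gibbs
      for (g in seq_len(G)) {
        idx <- g_of_s == g
        ng <- sum(idx)
        prec <- ng / sigma[g, ]^2 + 1 / s0^2
        mean_post <- (colSums(theta[idx, , drop = FALSE]) / sigma[g, ]^2 + m0 / s0^2) / prec
        mu[g, ] <- rnorm(P, mean_post, sqrt(1 / prec))
      }
      # --- group SDs: RW on log sigma with half-Normal(0, 1) prior
      for (g in seq_len(G)) {
        idx <- g_of_s == g
        th_g <- theta[idx, , drop = FALSE]
        ls <- log(sigma[g, ])
        ls_prop <- ls + rnorm(P, 0, sig_scale[g, ])
        cur <- colSums(dnorm(th_g, rep(mu[g, ], each = nrow(th_g)),
                             rep(exp(ls), each = nrow(th_g)), log = TRUE)) +
          dnorm(exp(ls), 0, 1, log = TRUE) + ls
        new <- colSums(dnorm(th_g, rep(mu[g, ], each = nrow(th_g)),
                             rep(exp(ls_prop), each = nrow(th_g)), log = TRUE)) +
          dnorm(exp(ls_prop), 0, 1, log = TRUE) + ls_prop
        take_s <- log(runif(P)) < (new - cur)
        sigma[g, take_s] <- exp(ls_prop[take_s])
      }
      if (it > mcmc$warmup && (it - mcmc$warmup) %% mcmc$thin == 0) {
        k <- k + 1
        mu_draws[k, ch, , ] <- mu
        sig_draws[k, ch, , ] <- sigma
        theta_draws[k, ch, , ] <- theta
        pw[(ch - 1) * n_save + k, ] <- ll_pointwise(theta)
      }
    }
  }

  # R-hat for every sampled scalar
  rhat <- c(
    array_rhat(mu_draws, paste0("mu[", rep(groups, P), ",",
                                rep(free, each = G), "]")),
    array_rhat(sig_draws, paste0("sigma[", rep(groups, P), ",",
                                 rep(free, each = G), "]")),
    array_rhat(theta_draws, paste0("theta[", rep(ids, P), ",",
                                   rep(free, each = S), "]"))
  )
  flag <- any(rhat > mcmc$rhat_threshold, na.rm = TRUE)
  if (flag) {
    warn(paste0("split R-hat above ", mcmc$rhat_threshold, " for ",
                sum(rhat > mcmc$rhat_threshold, na.rm = TRUE), " quantities."),
         class = "rs_convergence_warning")
  }

  structure(list(
    variant = variant, free = free, subject_ids = ids, groups = groups,
    group_of = setNames(grp, ids),
    mu_draws = mu_draws, sigma_draws = sig_draws, theta_draws = theta_draws,
    rhat = rhat, convergence_flag = flag,
    pointwise_loglik = pw,
    obs = choices %>% select("subject_id", "trial_id"),
    n_obs = n_obs, mcmc = mcmc, seed = seed
  ), class = "rs_hier_fit")
}

# expand a natural-parameter matrix [S x n_free] to the canonical 6 columns
canonical_matrix <- function(nat, variant, S) {
  one <- rep(1, S); zero <- rep(0, S)
  switch(variant,
    m0 = list(rho = nat[, "rho"], kappa_desc = one, kappa_exp = one,
              psi_safe = zero, psi_risky = zero, tau = nat[, "tau"]),
    m1 = list(rho = nat[, "rho"], kappa_desc = nat[, "kappa_desc"],
              kappa_exp = nat[, "kappa_exp"], psi_safe = one, psi_risky = one,
              tau = nat[, "tau"]),
    m2 = list(rho = nat[, "rho"], kappa_desc = nat[, "kappa_desc"],
              kappa_exp = nat[, "kappa_exp"], psi_safe = nat[, "psi_safe"],
              psi_risky = nat[, "psi_risky"], tau = nat[, "tau"]),
    m2s = list(rho = nat[, "rho"], kappa_desc = nat[, "kappa_desc"],
               kappa_exp = nat[, "kappa_exp"], psi_safe = nat[, "psi"],
               psi_risky = nat[, "psi"], tau = nat[, "tau"]),
    rs_abort(paste0("unknown model variant '", variant, "'."), "rs_config_error")
  )
}

array_rhat <- function(a, nms) {
  d <- dim(a)
  flat <- matrix(a, d[1] * d[2], prod(d[-(1:2)]))
  out <- vapply(seq_len(ncol(flat)), function(j) {
    split_rhat(matrix(flat[, j], d[1], d[2]))
  }, numeric(1))
  setNames(out, nms)
}

#' Posterior summaries of a hierarchical fit
#'
#' @param x An `rs_hier_fit`.
#' @param ... Unused.
#' @return `tidy()`: per-subject posterior means/SDs/95% intervals on the
#'   natural scale.  `group_means()`: posterior summaries of the
#'   group-level means (natural scale, i.e. `exp(mu)`).
#' @export
tidy.rs_hier_fit <- function(x, ...) {
  S <- length(x$subject_ids); P <- length(x$free)
  purrr::map_dfr(seq_len(P), function(p) {
    purrr::map_dfr(seq_len(S), function(s) {
      d <- exp(as.numeric(x$theta_draws[, , s, p]))
      tibble(
        subject_id = x$subject_ids[s],
        group = unname(x$group_of[x$subject_ids[s]]),
        parameter = x$free[p],
        estimate = mean(d), std_error = sd(d),
        conf_low = unname(quantile(d, 0.025)),
        conf_high = unname(quantile(d, 0.975))
      )
    })
  })
}

#' @rdname tidy.rs_hier_fit
#' @export
glance.rs_hier_fit <- function(x, ...) {
  tibble(
    variant = x$variant,
    n_subjects = length(x$subject_ids),
    n_obs = x$n_obs,
    n_draws = nrow(x$pointwise_loglik),
    max_rhat = max(x$rhat, na.rm = TRUE),
    convergence_flag = x$convergence_flag
  )
}

#' @rdname tidy.rs_hier_fit
#' @export
group_means <- function(x, ...) {
  stopifnot(inherits(x, "rs_hier_fit"))
  G <- length(x$groups); P <- length(x$free)
  purrr::map_dfr(seq_len(P), function(p) {
    purrr::map_dfr(seq_len(G), function(g) {
      d <- exp(as.numeric(x$mu_draws[, , g, p]))
      tibble(
        group = x$groups[g], parameter = x$free[p],
        estimate = mean(d),
        conf_low = unname(quantile(d, 0.025)),
        conf_high = unname(quantile(d, 0.975))
      )
    })
  })
}

#' @export
print.rs_hier_fit <- function(x, ...) {
  cat("<rs_hier_fit>", x$variant, "|", length(x$subject_ids), "subjects |",
      length(x$groups), "groups |", nrow(x$pointwise_loglik), "draws | max R-hat:",
      round(max(x$rhat, na.rm = TRUE), 4), "\n")
  invisible(x)
}
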