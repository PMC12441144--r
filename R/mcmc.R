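# Adaptive random-walk Metropolis machinery shared by the Bayesian fitters,
# plus the split-chain Gelman-Rubin diagnostic.

#' Split-chain R-hat
#'
#' Gelman-Rubin potential-scale-reduction statistic computed after
#' splitting each chain in half, so within-chain drift also registers as
#' non-convergence.
#'
#' @param draws A draws-by-chains numeric matrix for one scalar quantity.
#' @return The split-chain R-hat (NA for constant draws).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws) %/% 2
  if (n < 2) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(n), j], draws[n + seq_len(n), j])
  }))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  w <- mean(vars)
  b <- n * var(means)
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

# Adaptive RW-Metropolis over a fixed-dimension target.  Proposal scales
# adapt per coordinate-block (all coordinates jointly) toward a 0.3
# acceptance rate during warmup only.  Returns post-warmup thinned draws
# per chain plus acceptance rates.
run_mh <- function(log_post, init, chains = 4, iter = 1000, warmup = 500,
                   thin = 1, seed = 1, scale_init = 0.2) {
  n_par <- length(init)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  draws <- vector("list", chains)
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed((seed + 1009L * ch) %% .Machine$integer.max)
    th <- init + if (ch == 1) 0 else rnorm(n_par, 0, 0.3)
    lp <- log_post(th)
    if (!is.finite(lp)) { th <- init; lp <- log_post(th) }
    scale <- rep(scale_init, n_par)
    keep <- matrix(NA_real_, floor((iter - warmup) / thin), n_par)
    k <- 0; acc_win <- 0; n_win <- 0; n_acc_total <- 0
    for (it in seq_len(iter)) {
      prop <- th + rnorm(n_par, 0, scale)
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
        th <- prop; lp <- lp_prop
        acc_win <- acc_win + 1
        if (it > warmup) n_acc_total <- n_acc_total + 1
      }
      n_win <- n_win + 1
      if (it <= warmup && n_win == 50) {
        scale <- scale * exp((acc_win / n_win - 0.3))
        acc_win <- 0; n_win <- 0
      }
      if (it > warmup && (it - warmup) %% thin == 0) {
        k <- k + 1
        keep[k, ] <- th
      }
    }
    draws[[ch]] <- keep
    accept[ch] <- n_acc_total / (iter - warmup)
  }
  list(draws = draws, accept = accept)
}

#' MCMC configuration
#'
#' The `"desk"` preset (4 chains of 1000 iterations, 500 warmup) is a
#' scaled-down default for simulation studies and tests; the `"paper"`
#' preset uses 4 chains of 6000 iterations with 2000 warmup.
#'
#' @param chains,iter,warmup,thin Sampler settings.
#' @param preset `"desk"` or `"paper"`; explicit arguments override the
#'   preset.
#' @param rhat_threshold Convergence flag threshold (default 1.01).
#' @return A list of class `rs_mcmc_config`.
#' @export
mcmc_config <- function(chains = NULL, iter = NULL, warmup = NULL, thin = NULL,
                        preset = c("desk", "paper"), rhat_threshold = 1.01) {
  preset <- match.arg(preset)
  base <- if (preset == "desk") {
    list(chains = 4L, iter = 2000L, warmup = 1000L, thin = 4L)
  } else {
    list(chains = 4L, iter = 6000L, warmup = 2000L, thin = 8L)
  }
  out <- list(
    chains = chains %||% base$chains, iter = iter %||% base$iter,
    warmup = warmup %||% base$warmup, thin = thin %||% base$thin,
    preset = preset, rhat_threshold = rhat_threshold
  )
  if (out$warmup >= out$iter) rs_abort("warmup must be smaller than iter.", "rs_config_error")
  structure(out, class = "rs_mcmc_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bayesian fit of one subject by adaptive Metropolis sampling
#'
#' Samples the posterior of a single subject's transformed parameters under
#' the [prior_config()] priors, recording split-chain R-hat per parameter
#' and the draws-by-trials pointwise log-likelihood matrix used for
#' leave-one-trial-out cross-validation.
#'
#' @inheritParams fit_subject_map
#' @param mcmc An [mcmc_config()].
#' @return An object of class `rs_mcmc_fit` with `draws` (matrix over all
#'   chains), `rhat`, `pointwise_loglik`, posterior summaries and metadata.
#' @export
fit_subject_mcmc <- function(choices, variant = "m2", priors = prior_config(),
                             mcmc = mcmc_config(), seed = 1) {
  if (nrow(choices) < 1) rs_abort("need at least one trial.", "rs_domain_error")
  free <- variant_spec(variant)$free
  prep <- prep_trials(choices, variant)
  log_post <- function(th) {
    th <- setNames(th, free)
    theta_loglik(th, prep, variant) + log_prior(th, priors)
  }
  init <- prior_start(free, priors)
  res <- run_mh(log_post, init, chains = mcmc$chains, iter = mcmc$iter,
                warmup = mcmc$warmup, thin = mcmc$thin, seed = seed)
  per_chain <- lapply(res$draws, function(d) { colnames(d) <- free; d })
  rhat <- vapply(seq_along(free), function(j) {
    split_rhat(do.call(cbind, lapply(per_chain, function(d) d[, j])))
  }, numeric(1))
  names(rhat) <- free
  all_draws <- do.call(rbind, per_chain)
  pointwise <- t(apply(all_draws, 1, function(th) {
    theta_pointwise(setNames(th, free), prep, variant)
  }))
  flag <- any(rhat > mcmc$rhat_threshold, na.rm = TRUE)
  if (flag) {
    warn(paste0("split R-hat above ", mcmc$rhat_threshold,
                " for: ", paste(free[which(rhat > mcmc$rhat_threshold)], collapse = ", ")),
         class = "rs_convergence_warning")
  }
  structure(list(
    variant = variant,
    subject_id = if ("subject_id" %in% names(choices)) choices$subject_id[1] else NA_character_,
    draws = all_draws,
    rhat = rhat,
    convergence_flag = flag,
    accept = res$accept,
    pointwise_loglik = pointwise,
    n_obs = prep$n,
    mcmc = mcmc, seed = seed
  ), class = "rs_mcmc_fit")
}

#' @export
print.rs_mcmc_fit <- function(x, ...) {
  cat("<rs_mcmc_fit>", x$variant, "|", nrow(x$draws), "draws |",
      "max R-hat:", round(max(x$rhat, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' @rdname fit_subject_mcmc
#' @param x An `rs_mcmc_fit`.
#' @param ... Unused.
#' @export
tidy.rs_mcmc_fit <- function(x, ...) {
  free <- colnames(x$draws)
  purrr::map_dfr(free, function(nm) {
    d <- exp(x$draws[, nm])
    tibble(
      subject_id = x$subject_id, parameter = nm,
      estimate = mean(d), std_error = sd(d),
      conf_low = unname(quantile(d, 0.025)),
      conf_high = unname(quantile(d, 0.975)),
      rhat = unname(x$rhat[nm])
    )
  })
}

#' @rdname fit_subject_mcmc
#' @export
glance.rs_mcmc_fit <- function(x, ...) {
  tibble(variant = x$variant, n_obs = x$n_obs, n_draws = nrow(x$draws),
         max_rhat = max(x$rhat, na.rm = TRUE),
         convergence_flag = x$convergence_flag,
         mean_accept = mean(x$accept))
}
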