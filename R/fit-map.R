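#' Penalized maximum a posteriori fit for one subject
#'
#' Fast fitting path: maximizes the sum of per-trial Bernoulli
#' log-likelihoods plus the log prior on the transformed (log) parameter
#' scale, taking the best of `n_starts` jittered multistarts
#' (deterministic given `seed`).  A Laplace approximation around the mode
#' (multivariate-Normal draws from the inverse Hessian) supplies a
#' draws-by-trials pointwise log-likelihood matrix so that approximate
#' leave-one-trial-out cross-validation can penalize model complexity even
#' on this non-MCMC path.
#'
#' Degenerate data (all choices identical) and estimates within 0.05 of
#' the transformed-scale optimization bounds are flagged in the result
#' rather than silently returned.
#'
#' @param choices Choice tibble for a single subject (columns as produced
#'   by [simulate_choices()]: `value_risky`, `p_win`, `condition`, `social`,
#'   `safe_value`, `choice`).
#' @param variant Model variant id (see [model_variants()]).
#' @param priors A [prior_config()] object.
#' @param n_starts Number of optimizer multistarts.
#' @param seed Integer seed for the start jitter and Laplace draws.
#' @param laplace_draws Number of posterior-approximation draws (0 gives a
#'   pure point fit whose pointwise matrix has a single row).
#' @param bounds Transformed-scale box constraints for the optimizer.
#' @return An object of class `rs_map_fit`: estimates on both scales, the
#'   maximized log posterior/likelihood, flags, draws and the pointwise
#'   log-likelihood matrix.
#' @export
fit_subject_map <- function(choices, variant = "m2", priors = prior_config(),
                            n_starts = 3, seed = 1, laplace_draws = 400,
                            bounds = c(-7, 7)) {
  if (nrow(choices) < 1) rs_abort("need at least one trial.", "rs_domain_error")
  free <- variant_spec(variant)$free
  prep <- prep_trials(choices, variant)
  neg_post <- function(th) {
    th <- setNames(th, free)
    val <- -(theta_loglik(th, prep, variant) + log_prior(th, priors))
    if (!is.finite(val)) 1e10 else val # utility overflow at extreme rho
  }
  start0 <- prior_start(free, priors)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(k) {
    if (k == 1) start0 else start0 + rnorm(length(free), 0, 0.5)
  })
  fits <- lapply(starts, function(s) {
    tryCatch(
      optim(s, neg_post, method = "L-BFGS-B",
            lower = bounds[1], upper = bounds[2],
            control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    rs_abort("all optimizer starts failed.", "rs_optim_error")
  }
  best <- fits[[which.min(vapply(fits, function(f) f$value, numeric(1)))]]
  theta <- setNames(best$par, free)

  boundary <- any(abs(theta - bounds[1]) < 0.05 | abs(theta - bounds[2]) < 0.05)
  degenerate <- length(unique(prep$y)) == 1

  hess <- tryCatch(
    optim(theta, neg_post, method = "L-BFGS-B", lower = bounds[1],
          upper = bounds[2], control = list(maxit = 1), hessian = TRUE)$hessian,
    error = function(e) NULL
  )
  draws <- matrix(theta, nrow = 1, dimnames = list(NULL, free))
  if (laplace_draws > 0 && !is.null(hess)) {
    cov <- laplace_cov(hess)
    z <- matrix(rnorm(laplace_draws * length(free)), laplace_draws)
    draws <- sweep(z %*% chol(cov), 2, theta, "+")
    colnames(draws) <- free
  }
  pointwise <- t(apply(draws, 1, function(th) {
    theta_pointwise(setNames(th, free), prep, variant)
  }))
  if (nrow(draws) == 1) pointwise <- matrix(pointwise, nrow = 1)

  structure(list(
    variant = variant,
    subject_id = if ("subject_id" %in% names(choices)) choices$subject_id[1] else NA_character_,
    theta = theta,
    params = canonical_params(theta_to_params(theta, variant), variant),
    logpost = -best$value,
    loglik = theta_loglik(theta, prep, variant),
    n_obs = prep$n,
    converged = best$convergence == 0,
    boundary_flag = boundary,
    degenerate_data = degenerate,
    draws = draws,
    pointwise_loglik = pointwise,
    seed = seed
  ), class = "rs_map_fit")
}

# symmetrize + ridge an optim Hessian into a usable covariance
laplace_cov <- function(hess) {
  h <- (hess + t(hess)) / 2
  ridge <- 1e-6
  for (i in 1:8) {
    cov <- tryCatch(solve(h + diag(ridge, nrow(h))), error = function(e) NULL)
    if (!is.null(cov) && all(eigen(cov, symmetric = TRUE, only.values = TRUE)$values > 0)) {
      return((cov + t(cov)) / 2)
    }
    ridge <- ridge * 10
  }
  diag(0.05, nrow(h))
}

#' Penalized MAP fits for every subject in a dataset
#'
#' Applies [fit_subject_map()] to each subject and assembles a combined
#' pointwise log-likelihood matrix (subjects are independent, so their
#' Laplace draws are concatenated column-wise) ordered by subject then
#' trial.
#'
#' @inheritParams fit_subject_map
#' @param choices Choice tibble for the whole dataset with a `subject_id`
#'   column.
#' @return An object of class `rs_map_fits` containing the per-subject
#'   fits, the combined pointwise matrix, and the observation index.
#' @export
fit_map <- function(choices, variant = "m2", priors = prior_config(),
                    n_starts = 3, seed = 1, laplace_draws = 400) {
  ids <- unique(choices$subject_id)
  fits <- purrr::imap(setNames(ids, ids), function(id, nm) {
    fit_subject_map(choices %>% filter(.data$subject_id == id),
                    variant, priors, n_starts,
                    seed = (seed + 613L * match(id, ids)) %% .Machine$integer.max,
                    laplace_draws = laplace_draws)
  })
  pw <- do.call(cbind, lapply(fits, function(f) f$pointwise_loglik))
  obs <- choices %>%
    arrange(match(.data$subject_id, ids), .data$trial_id) %>%
    select("subject_id", "trial_id")
  structure(list(
    variant = variant, fits = fits,
    pointwise_loglik = pw, obs = obs, seed = seed
  ), class = "rs_map_fits")
}

#' @export
print.rs_map_fit <- function(x, ...) {
  cat("<rs_map_fit>", x$variant, "| subject:", x$subject_id,
      "| logpost:", round(x$logpost, 2),
      if (x$boundary_flag) "| BOUNDARY" else "",
      if (x$degenerate_data) "| DEGENERATE DATA" else "", "\n")
  print(round(unlist(x$params), 4))
  invisible(x)
}

#' @export
print.rs_map_fits <- function(x, ...) {
  cat("<rs_map_fits>", x$variant, "|", length(x$fits), "subjects |",
      ncol(x$pointwise_loglik), "observations\n")
  invisible(x)
}

#' @rdname fit_subject_map
#' @param x An `rs_map_fit` / `rs_map_fits` object.
#' @param ... Unused.
#' @export
tidy.rs_map_fit <- function(x, ...) {
  tibble(
    subject_id = x$subject_id,
    parameter = names(x$theta),
    estimate = exp(unname(x$theta)),
    transformed = unname(x$theta)
  )
}

#' @rdname fit_subject_map
#' @export
tidy.rs_map_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy)
}

#' @rdname fit_subject_map
#' @export
glance.rs_map_fit <- function(x, ...) {
  tibble(variant = x$variant, n_obs = x$n_obs, loglik = x$loglik,
         logpost = x$logpost, converged = x$converged,
         boundary_flag = x$boundary_flag, degenerate_data = x$degenerate_data)
}

#' @rdname fit_subject_map
#' @export
glance.rs_map_fits <- function(x, ...) {
  tibble(
    variant = x$variant,
    n_subjects = length(x$fits),
    n_obs = ncol(x$pointwise_loglik),
    loglik = sum(vapply(x$fits, function(f) f$loglik, numeric(1))),
    any_boundary = any(vapply(x$fits, function(f) f$boundary_flag, logical(1))),
    any_degenerate = any(vapply(x$fits, function(f) f$degenerate_data, logical(1)))
  )
}
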