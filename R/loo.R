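# Approximate leave-one-trial-out cross-validation via Pareto-smoothed
# importance sampling, with the Zhang & Stephens (2009) profile-likelihood
# fit of the generalized Pareto distribution to the importance-weight tail.

# GPD fit to exceedances x (all > 0); returns shape k and scale sigma
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30 + floor(sqrt(n))
  q1 <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * q1)
  k_of <- function(th) -mean(log1p(-th * x))
  prof <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(prof - prof[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- k_of(theta_hat)
  sigma <- k / theta_hat
  # weak-prior regularization of the shape toward 0.5 (stabilizes small tails)
  k <- (n * k + 5 * 0.5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) sigma * (-log1p(-p)) else sigma * expm1(-k * log1p(-p)) / k
}

# smooth the largest importance log-weights of one observation; returns the
# smoothed log-weights and the tail-shape diagnostic k-hat
psis_smooth <- function(lw) {
  s <- length(lw)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (m < 5) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_idx <- ord[(s - m + 1):s]
  cutoff <- lw[ord[s - m]]
  exc <- exp(lw[tail_idx]) - exp(cutoff)
  if (sd(exc) < 1e-12 || all(exc <= 0)) return(list(lw = lw, k = NA_real_))
  fit <- gpd_fit(exc[exc > 0])
  # replace tail by expected order statistics of the fitted GPD
  qs <- qgpd((seq_len(m) - 0.5) / m, fit$k, fit$sigma)
  sm <- log(exp(cutoff) + qs)
  sm <- pmin(sm, max(lw))
  if (!all(is.finite(sm)) || !is.finite(fit$k)) {
    return(list(lw = lw, k = NA_real_)) # degenerate tail: leave weights raw
  }
  lw[tail_idx[order(lw[tail_idx])]] <- sm
  list(lw = lw, k = fit$k)
}

#' PSIS leave-one-out cross-validation from a pointwise log-likelihood matrix
#'
#' Computes the expected log pointwise predictive density under approximate
#' leave-one-trial-out cross-validation by importance sampling, smoothing
#' the tail of each observation's importance weights with a fitted
#' generalized Pareto distribution.  Observations whose tail-shape
#' diagnostic exceeds 0.7 are flagged as unreliable (a note is attached;
#' no silent substitution is made).  `looic = -2 * elpd_loo`.
#'
#' A single-row matrix (a point fit) takes the degenerate path: `elpd` is
#' the plain sum of log-likelihoods and the result is flagged
#' `point_estimate = TRUE`, i.e. not a Bayesian LOO.
#'
#' @param loglik A draws-by-observations matrix of pointwise
#'   log-likelihoods.
#' @return An object of class `rs_loo`: `elpd_loo`, `se_elpd`, `looic`,
#'   `se_looic`, `p_loo`, and a `pointwise` tibble with per-observation
#'   `elpd_i`, `k_hat` and `flagged`.
#' @examples
#' ll <- matrix(rnorm(200, -0.7, 0.05), 10, 20)
#' loo_from_pointwise(ll)
#' @export
loo_from_pointwise <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (!all(is.finite(loglik))) {
    rs_abort("pointwise log-likelihoods must be finite.", "rs_input_error")
  }
  n <- ncol(loglik)
  s <- nrow(loglik)
  if (s == 1) {
    elpd_i <- as.numeric(loglik)
    pw <- tibble(obs = seq_len(n), elpd_i = elpd_i,
                 k_hat = NA_real_, flagged = FALSE)
    out <- list(
      elpd_loo = sum(elpd_i), se_elpd = sd(elpd_i) * sqrt(n),
      looic = -2 * sum(elpd_i), se_looic = 2 * sd(elpd_i) * sqrt(n),
      p_loo = NA_real_, pointwise = pw,
      n_obs = n, n_draws = 1, point_estimate = TRUE
    )
    return(structure(out, class = "rs_loo"))
  }
  elpd_i <- numeric(n)
  k_hat <- numeric(n)
  lpd_i <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll) # raw log importance weights are -loglik
    lw <- sm$lw - log_sum_exp(sm$lw)
    elpd_i[i] <- log_sum_exp(lw + ll)
    lpd_i[i] <- log_sum_exp(ll) - log(s)
    k_hat[i] <- sm$k
  }
  flagged <- !is.na(k_hat) & k_hat > 0.7
  if (any(flagged)) {
    warn(paste0(sum(flagged), " of ", n,
                " observations have Pareto k-hat > 0.7; their LOO estimates",
                " may be unreliable."),
         class = "rs_psis_warning")
  }
  structure(list(
    elpd_loo = sum(elpd_i), se_elpd = sd(elpd_i) * sqrt(n),
    looic = -2 * sum(elpd_i), se_looic = 2 * sd(elpd_i) * sqrt(n),
    p_loo = sum(lpd_i - elpd_i),
    pointwise = tibble(obs = seq_len(n), elpd_i = elpd_i,
                       k_hat = k_hat, flagged = flagged),
    n_obs = n, n_draws = s, point_estimate = FALSE
  ), class = "rs_loo")
}

#' @export
print.rs_loo <- function(x, ...) {
  cat("<rs_loo> elpd_loo:", round(x$elpd_loo, 2),
      "(se", paste0(round(x$se_elpd, 2), ")"),
      "| looic:", round(x$looic, 2),
      if (x$point_estimate) "| POINT-ESTIMATE PATH (non-Bayesian)" else "", "\n")
  invisible(x)
}

#' @rdname loo_from_pointwise
#' @param x An `rs_loo`.
#' @param ... Unused.
#' @export
glance.rs_loo <- function(x, ...) {
  tibble(elpd_loo = x$elpd_loo, se_elpd = x$se_elpd, looic = x$looic,
         p_loo = x$p_loo, n_obs = x$n_obs, n_draws = x$n_draws,
         n_flagged = sum(x$pointwise$flagged),
         point_estimate = x$point_estimate)
}

# pointwise log-likelihood matrix of any fit object
pointwise_matrix <- function(fit) {
  if (inherits(fit, "rs_loo")) rs_abort("expected a fit, not an rs_loo.", "rs_input_error")
  if (!is.null(fit$pointwise_loglik)) return(fit$pointwise_loglik)
  rs_abort("fit object carries no pointwise log-likelihood matrix.", "rs_input_error")
}

#' Compare fitted model variants by looic
#'
#' Runs [loo_from_pointwise()] on each fit's pointwise matrix and tabulates
#' elpd / looic with standard errors, plus the pairwise elpd difference to
#' the best variant with the SE of the paired pointwise differences.
#'
#' @param fits Named list of fit objects (`rs_map_fits`, `rs_hier_fit`,
#'   `rs_mcmc_fit`) computed on the identical observation set.  Names
#'   default to each fit's `variant`.
#' @return A tibble of class `rs_compare`, sorted by decreasing elpd:
#'   `variant`, `elpd_loo`, `se_elpd`, `looic`, `elpd_diff`, `se_diff`,
#'   `n_flagged`.
#' @export
compare_variants <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$variant, character(1))
  }
  mats <- lapply(fits, pointwise_matrix)
  n_obs <- vapply(mats, ncol, integer(1))
  if (length(unique(n_obs)) != 1) {
    rs_abort("fits were computed on different observation sets.",
             "rs_comparison_error")
  }
  loos <- lapply(mats, function(m) suppressWarnings(loo_from_pointwise(m)))
  tab <- purrr::imap_dfr(loos, function(l, nm) {
    tibble(variant = nm, elpd_loo = l$elpd_loo, se_elpd = l$se_elpd,
           looic = l$looic, n_flagged = sum(l$pointwise$flagged))
  }) %>% arrange(dplyr::desc(.data$elpd_loo))
  best <- tab$variant[1]
  best_pw <- loos[[best]]$pointwise$elpd_i
  tab <- tab %>%
    mutate(
      elpd_diff = .data$elpd_loo - tab$elpd_loo[1],
      se_diff = vapply(.data$variant, function(v) {
        d <- loos[[v]]$pointwise$elpd_i - best_pw
        if (all(d == 0)) 0 else sd(d) * sqrt(length(d))
      }, numeric(1), USE.NAMES = FALSE)
    )
  attr(tab, "loos") <- loos
  class(tab) <- c("rs_compare", class(tab))
  tab
}

#' @export
print.rs_compare <- function(x, ...) {
  cat("<rs_compare> leave-one-trial-out model comparison\n")
  NextMethod()
}

#' Model-recovery confusion study
#'
#' For each generating variant, simulates a fresh population and dataset,
#' fits every candidate variant by the penalized-MAP/Laplace path, and
#' records which variant wins the looic comparison.  Diagonal dominance of
#' the resulting confusion matrix indicates that the comparison can
#' identify the data-generating model at the simulated effect sizes.
#'
#' @param generating Variants to simulate from.
#' @param candidates Variants fitted to every dataset.
#' @param n_reps Replicates per generating variant.
#' @param n_subjects Subjects per replicate.
#' @param age_model Age-trend generator for the populations.
#' @param design Trial design (default full 144-trial design).
#' @param seed Integer seed.
#' @param n_starts,laplace_draws Passed to [fit_map()].
#' @return A tibble of class `rs_recovery`: one row per replicate with
#'   `generating`, `rep`, `winner`, and the elpd of each candidate;
#'   `confusion_matrix()` tabulates winner frequencies.
#' @export
model_recovery <- function(generating = c("m0", "m2"),
                           candidates = c("m0", "m1", "m2"),
                           n_reps = 10, n_subjects = 20,
                           age_model = age_trend_config(),
                           design = build_design(), seed = 1,
                           n_starts = 2, laplace_draws = 300) {
  if (n_reps < 1) rs_abort("`n_reps` must be at least 1.", "rs_config_error")
  pool <- build_advisor_pool(design = design, seed = seed + 99L)
  rows <- purrr::map_dfr(generating, function(gen) {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      rseed <- (seed + 7001L * r + 37L * match(gen, generating)) %% .Machine$integer.max
      pop <- simulate_population(n_subjects, age_model, seed = rseed)
      sim <- simulate_study(pop, design, pool = pool, variant = gen, seed = rseed + 1L)
      fits <- lapply(setNames(candidates, candidates), function(v) {
        fit_map(sim$choices, v, n_starts = n_starts, seed = rseed + 2L,
                laplace_draws = laplace_draws)
      })
      tab <- compare_variants(fits)
      elpds <- setNames(tab$elpd_loo[match(candidates, tab$variant)],
                        paste0("elpd_", candidates))
      attr(tab, "loos") <- NULL
      dplyr::bind_cols(
        tibble(generating = gen, rep = r, winner = tab$variant[1]),
        as_tibble(as.list(elpds)),
        tibble(comparison = list(as_tibble(tab)))
      )
    })
  })
  class(rows) <- c("rs_recovery", class(rows))
  rows
}

#' @rdname model_recovery
#' @param recovery An `rs_recovery` tibble.
#' @export
confusion_matrix <- function(recovery) {
  recovery %>%
    count(.data$generating, .data$winner) %>%
    tidyr::pivot_wider(names_from = "winner", values_from = "n",
                       values_fill = 0)
}
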