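# Leave-one-out model comparison via Pareto-smoothed importance sampling,
# with an AIC fallback for point-estimate (MLE) fits.

# Zhang & Stephens (2009)-style empirical-Bayes fit of the generalized
# Pareto distribution to tail exceedances. Returns the usual (xi, sigma)
# parameterization with cdf 1 - (1 + xi x / sigma)^(-1/xi).
gpd_fit <- function(x) {
  n <- length(x)
  x <- sort.int(x)
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of_b <- vapply(b, function(bi) -mean(log1p(-bi * x)), numeric(1))
  l_b <- n * (log(b / k_of_b) + k_of_b - 1)
  w <- exp(l_b - log_sum_exp(l_b))
  b_hat <- sum(b * w)
  k_hat <- -mean(log1p(-b_hat * x))
  xi <- -k_hat
  sigma <- k_hat / b_hat
  list(xi = xi, sigma = sigma)
}

qgpd <- function(p, xi, sigma) {
  if (abs(xi) < 1e-12) {
    -sigma * log1p(-p)
  } else {
    sigma * expm1(-xi * log1p(-p)) / xi
  }
}

# Pareto-smooth one vector of log importance ratios. Returns the smoothed
# log weights and the estimated tail-shape diagnostic.
psis_smooth <- function(log_ratios) {
  s <- length(log_ratios)
  lw <- log_ratios - max(log_ratios)
  tail_len <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (tail_len < 5) {
    return(list(log_weights = lw, pareto_k = Inf))
  }
  ord <- order(lw)
  tail_idx <- ord[(s - tail_len + 1):s]
  cutoff <- lw[ord[s - tail_len]]
  exceed <- exp(lw[tail_idx]) - exp(cutoff)
  if (all(exceed <= 0) || stats::sd(exceed) == 0) {
    # (near-)flat tail: raw weights are bounded and reliable as they stand
    return(list(log_weights = lw, pareto_k = 0))
  }
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$xi) || !is.finite(fit$sigma) || fit$sigma <= 0) {
    return(list(log_weights = lw, pareto_k = 0))
  }
  p <- (seq_len(tail_len) - 0.5) / tail_len
  smoothed <- log(exp(cutoff) + qgpd(p, fit$xi, fit$sigma))
  # assign expected order statistics in rank order, truncated at the
  # largest raw weight
  smoothed <- pmin(smoothed, 0)
  lw[tail_idx[order(lw[tail_idx])]] <- smoothed
  list(log_weights = lw, pareto_k = fit$xi)
}

#' PSIS leave-one-out model assessment
#'
#' Estimates the expected log pointwise predictive density (elpd) by
#' Pareto-smoothed importance sampling over posterior draws: for each
#' observation the importance ratios `1 / p(y_i | theta_s)` are tail-
#' smoothed by a generalized Pareto fit before self-normalized weighting.
#' LOOIC is `-2 * elpd`; the per-observation Pareto tail-shape estimates
#' are reported as reliability diagnostics (values above 0.7 are the
#' conventional warning level).
#'
#' @param log_lik Matrix of pointwise log-likelihoods, draws x observations
#'   (at least 2 draws). A constant (degenerate) column is an error.
#' @param label Optional grouping label carried into summaries.
#' @return An object of class `srl_loo` with `elpd`, `se`, `looic`,
#'   `looic_se`, `n_obs`, `n_draws` and a `pointwise` tibble (`elpd_i`,
#'   `pareto_k`).
#' @examples
#' ll <- matrix(rnorm(2000, mean = -1), nrow = 100)
#' loo_psis(ll)
#' @export
loo_psis <- function(log_lik, label = NULL) {
  log_lik <- as.matrix(log_lik)
  if (nrow(log_lik) < 2) {
    abort("loo_psis() needs at least 2 posterior draws; MLE fits should be compared with compare_fits() (AIC fallback)",
          class = "srl_loo_error")
  }
  if (ncol(log_lik) < 1) abort("No observations", class = "srl_loo_error")
  constant <- apply(log_lik, 2, function(x) max(x) - min(x) == 0)
  if (all(constant)) {
    abort("Degenerate draws: every observation's log-likelihood is constant across draws",
          class = "srl_loo_error")
  }
  res <- apply(log_lik, 2, function(ll) {
    if (max(ll) - min(ll) == 0) {
      # no posterior uncertainty for this observation (e.g. a first trial
      # whose choice probability is parameter-free): exact elpd, no tail
      return(c(ll[1], 0))
    }
    sm <- psis_smooth(-ll)
    elpd_i <- log_sum_exp(ll + sm$log_weights) - log_sum_exp(sm$log_weights)
    c(elpd_i, sm$pareto_k)
  })
  pointwise <- tibble::tibble(elpd_i = res[1, ], pareto_k = res[2, ])
  n <- ncol(log_lik)
  elpd <- sum(pointwise$elpd_i)
  se <- sqrt(n * stats::var(pointwise$elpd_i))
  structure(
    list(elpd = elpd, se = se, looic = -2 * elpd, looic_se = 2 * se,
         n_obs = n, n_draws = nrow(log_lik), label = label,
         pointwise = pointwise),
    class = "srl_loo"
  )
}

#' @export
print.srl_loo <- function(x, ...) {
  cat("<srl_loo>", if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  elpd %.2f (SE %.2f)  LOOIC %.2f  (%d obs, %d draws)\n",
              x$elpd, x$se, x$looic, x$n_obs, x$n_draws))
  k <- x$pointwise$pareto_k
  cat(sprintf("  pareto k: %d of %d > 0.7\n", sum(k > 0.7), length(k)))
  invisible(x)
}

#' @describeIn loo_psis One-row summary tibble of the estimate.
#' @param x An `srl_loo` object.
#' @export
glance.srl_loo <- function(x, ...) {
  tibble::tibble(
    label = x$label %||% NA_character_,
    elpd = x$elpd, se = x$se, looic = x$looic, looic_se = x$looic_se,
    n_obs = x$n_obs, n_draws = x$n_draws,
    n_high_pareto_k = sum(x$pointwise$pareto_k > 0.7)
  )
}

#' Compare two LOO assessments of the same observations
#'
#' Computes the LOOIC difference `looic_a - looic_b` with the paired
#' standard error over pointwise elpd differences. The preferred model is
#' the one with the lower LOOIC; when the absolute difference is smaller
#' than its standard error, the fits are flagged as relatively similar.
#'
#' @param loo_a,loo_b Two [loo_psis()] results computed on the same set of
#'   observations (mismatched counts are an error).
#' @param labels Length-2 labels for the two models.
#' @return A one-row tibble with `delta_looic`, `se_delta`, `preferred`
#'   and `similar_fit`.
#' @export
compare_loo <- function(loo_a, loo_b, labels = c("a", "b")) {
  stopifnot(inherits(loo_a, "srl_loo"), inherits(loo_b, "srl_loo"))
  if (loo_a$n_obs != loo_b$n_obs) {
    abort("The two models were assessed on different numbers of observations",
          class = "srl_loo_error")
  }
  diff_i <- loo_a$pointwise$elpd_i - loo_b$pointwise$elpd_i
  delta <- loo_a$looic - loo_b$looic
  se_delta <- 2 * sqrt(loo_a$n_obs * stats::var(diff_i))
  tibble::tibble(
    model_a = labels[1], model_b = labels[2],
    looic_a = loo_a$looic, looic_b = loo_b$looic,
    delta_looic = delta, se_delta = se_delta,
    preferred = ifelse(delta <= 0, labels[1], labels[2]),
    similar_fit = abs(delta) < se_delta | delta == 0
  )
}

#' Compare single- and dual-learning-rate fits per condition and session
#'
#' For Bayesian fits carrying pointwise log-likelihood draws, runs
#' [loo_psis()] within each grouping cell (the pointwise unit is the trial)
#' and compares LOOIC with paired standard errors. For MLE fits (a single
#' pseudo-draw) this comparison degenerates, so an AIC fallback is computed
#' per cell instead and clearly labeled as such.
#'
#' @param fit_a,fit_b Two `srl_fit` objects for the same trials (e.g. the
#'   single- and dual-learning-rate models).
#' @param by Grouping columns among `condition`, `session` (default both);
#'   use `character(0)` for a single overall comparison.
#' @return A tibble with one row per group: the criterion used (`"looic"`
#'   or `"aic"`), per-model values, the difference, its SE (LOO only), the
#'   preferred model and the similar-fit flag.
#' @export
compare_fits <- function(fit_a, fit_b, by = c("condition", "session")) {
  stopifnot(inherits(fit_a, "srl_fit"), inherits(fit_b, "srl_fit"))
  labels <- c(fit_a$model, fit_b$model)
  pa <- pointwise_loglik(fit_a)
  pb <- pointwise_loglik(fit_b)
  if (ncol(pa$log_lik) != ncol(pb$log_lik)) {
    abort("Fits cover different numbers of observations",
          class = "srl_loo_error")
  }
  groups <- if (length(by) == 0) {
    tibble::tibble(.group = "all")
  } else {
    dplyr::distinct(pa$obs[, by, drop = FALSE])
  }

  purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    if (length(by) == 0) {
      idx <- seq_len(ncol(pa$log_lik))
      meta <- tibble::tibble(.rows = 1)
    } else {
      sel <- rep(TRUE, nrow(pa$obs))
      for (v in by) sel <- sel & pa$obs[[v]] == groups[[v]][g]
      idx <- which(sel)
      meta <- groups[g, , drop = FALSE]
    }
    if (nrow(pa$log_lik) >= 2 && nrow(pb$log_lik) >= 2) {
      cmp <- compare_loo(loo_psis(pa$log_lik[, idx, drop = FALSE]),
                         loo_psis(pb$log_lik[, idx, drop = FALSE]),
                         labels = labels)
      dplyr::bind_cols(meta, tibble::tibble(criterion = "looic"),
                       cmp[, c("looic_a", "looic_b", "delta_looic",
                               "se_delta", "preferred", "similar_fit")] |>
                         dplyr::rename(value_a = "looic_a", value_b = "looic_b",
                                       delta = "delta_looic"))
    } else {
      k_a <- if (fit_a$model == "dual") 3 else 2
      k_b <- if (fit_b$model == "dual") 3 else 2
      n_units <- function(p, idx) {
        dplyr::n_distinct(p$obs$subject_id[idx], p$obs$session[idx])
      }
      aic_a <- -2 * sum(pa$log_lik[1, idx]) + 2 * k_a * n_units(pa, idx)
      aic_b <- -2 * sum(pb$log_lik[1, idx]) + 2 * k_b * n_units(pb, idx)
      delta <- aic_a - aic_b
      dplyr::bind_cols(meta, tibble::tibble(
        criterion = "aic", value_a = aic_a, value_b = aic_b,
        delta = delta, se_delta = NA_real_,
        preferred = ifelse(delta <= 0, labels[1], labels[2]),
        similar_fit = NA
      ))
    }
  })
}
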