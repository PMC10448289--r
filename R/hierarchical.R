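# Hierarchical Bayesian estimation of the Q-learning models: partial
# pooling of subject-session parameters on transformed scales via an
# adaptive random-walk Metropolis-within-Gibbs sampler.
#
# Model (transformed scales: logit learning rates, log inverse temperature
# capped at beta_max):
#   theta_j ~ Normal(mu, diag(sigma^2))   per subject-session unit j
#   mu_d    ~ Normal(0, 1)
#   sigma_d ~ half-Normal(1)
# Unit parameters are updated by joint random-walk proposals against their
# trial likelihood; mu has a conjugate normal draw and log sigma a cheap
# scalar Metropolis step (neither needs the trial likelihoods), which is
# why the sampler uses the centered parameterization.

unit_loglik <- function(theta, idx, model, beta_max, q0) {
  -nll_transformed(theta, idx, model, beta_max, q0)
}

#' Hierarchical Bayesian Q-learning fit
#'
#' Fits the dual- or single-learning-rate Q-learning model to all supplied
#' subject-sessions at once, partially pooling parameters through group-
#' level location and scale priors on the transformed scales (weakly
#' informative: Normal(0,1) means, half-Normal(1) scales). Sampling is by
#' adaptive random-walk Metropolis within Gibbs; posterior draws of the
#' pointwise log-likelihoods are retained for LOOIC model comparison.
#' Convergence is monitored by split R-hat on the group means and by
#' acceptance rates; problems are carried in the result (and raised as a
#' warning), never silent.
#'
#' @param trials A validated trial table (training phase is modeled); at
#'   least 2 subject-session units are required.
#' @param model `"dual"` or `"single"`.
#' @param iter,warmup Total and warmup Metropolis sweeps.
#' @param keep_draws Number of post-warmup draws (evenly thinned) on which
#'   pointwise log-likelihoods are evaluated.
#' @param seed RNG seed; identical data and seed give identical draws.
#' @param beta_max Cap on the inverse temperature.
#' @return An `srl_fit` with posterior-mean `estimates` per unit, a
#'   `log_lik` draws x trials matrix with its `obs` bookkeeping, `group`
#'   posterior summaries, and `diagnostics` (R-hat, acceptance rates,
#'   `convergence_warning`).
#' @export
fit_hierarchical <- function(trials, model = c("dual", "single"),
                             iter = 1500, warmup = 500, keep_draws = 400,
                             seed = 1, beta_max = 20) {
  model <- match.arg(model)
  validate_trials(trials)
  train <- trials |>
    dplyr::filter(.data$phase == "train") |>
    dplyr::arrange(.data$subject_id, .data$session, .data$trial_index)
  units <- train |>
    dplyr::distinct(.data$subject_id, .data$condition, .data$session)
  J <- nrow(units)
  if (J < 2) {
    abort("fit_hierarchical() needs at least 2 subject-session units",
          class = "srl_fit_error")
  }
  k <- if (model == "dual") 3L else 2L
  q0 <- rep(0.5, length(srl_faces()))
  idx_list <- purrr::map(seq_len(J), function(j) {
    trials_to_indices(
      dplyr::filter(train, .data$subject_id == units$subject_id[j],
                    .data$session == units$session[j])
    )
  })

  with_seed(seed, {
    # initialization near weakly informative center
    theta <- matrix(rnorm(J * k, 0, 0.3), J, k)
    theta[, k] <- theta[, k] + log(3)  # beta near 3
    mu <- colMeans(theta)
    sigma <- rep(0.5, k)
    ll_unit <- vapply(seq_len(J), function(j) {
      unit_loglik(theta[j, ], idx_list[[j]], model, beta_max, q0)
    }, numeric(1))

    step_unit <- rep(0.3, J)
    step_sigma <- rep(0.5, k)
    acc_unit <- rep(0, J)
    acc_sigma <- rep(0, k)
    n_post <- iter - warmup
    keep_at <- unique(round(seq(warmup + 1, iter, length.out = min(keep_draws, n_post))))
    theta_draws <- array(NA_real_, c(length(keep_at), J, k))
    mu_draws <- matrix(NA_real_, length(keep_at), k)
    sigma_draws <- matrix(NA_real_, length(keep_at), k)
    kept <- 0L

    for (it in seq_len(iter)) {
      # unit-level joint random-walk updates
      for (j in seq_len(J)) {
        prop <- theta[j, ] + rnorm(k, 0, step_unit[j])
        ll_prop <- unit_loglik(prop, idx_list[[j]], model, beta_max, q0)
        log_r <- (ll_prop + sum(stats::dnorm(prop, mu, sigma, log = TRUE))) -
          (ll_unit[j] + sum(stats::dnorm(theta[j, ], mu, sigma, log = TRUE)))
        if (is.finite(log_r) && log(runif(1)) < log_r) {
          theta[j, ] <- prop
          ll_unit[j] <- ll_prop
          acc_unit[j] <- acc_unit[j] + 1
        }
        if (it <= warmup && it %% 20 == 0) {
          rate <- acc_unit[j] / it
          step_unit[j] <- step_unit[j] * exp(0.5 * (rate - 0.3))
        }
      }
      # conjugate normal draw for mu (prior N(0,1))
      prec <- J / sigma^2 + 1
      mu_mean <- (colSums(theta) / sigma^2) / prec
      mu <- rnorm(k, mu_mean, sqrt(1 / prec))
      # scalar Metropolis on log sigma (prior half-Normal(1))
      for (d in seq_len(k)) {
        ls_prop <- log(sigma[d]) + rnorm(1, 0, step_sigma[d])
        s_prop <- exp(ls_prop)
        log_r <- sum(stats::dnorm(theta[, d], mu[d], s_prop, log = TRUE)) -
          sum(stats::dnorm(theta[, d], mu[d], sigma[d], log = TRUE)) +
          stats::dnorm(s_prop, 0, 1, log = TRUE) -
          stats::dnorm(sigma[d], 0, 1, log = TRUE) +
          ls_prop - log(sigma[d])  # Jacobian of the log transform
        if (is.finite(log_r) && log(runif(1)) < log_r) {
          sigma[d] <- s_prop
          acc_sigma[d] <- acc_sigma[d] + 1
        }
        if (it <= warmup && it %% 20 == 0) {
          rate <- acc_sigma[d] / it
          step_sigma[d] <- step_sigma[d] * exp(0.5 * (rate - 0.35))
        }
      }
      if (it %in% keep_at) {
        kept <- kept + 1L
        theta_draws[kept, , ] <- theta
        mu_draws[kept, ] <- mu
        sigma_draws[kept, ] <- sigma
      }
    }

    # pointwise log-likelihoods on the kept draws
    n_obs_unit <- vapply(idx_list, function(x) length(x$a), integer(1))
    log_lik <- matrix(NA_real_, kept, sum(n_obs_unit))
    offsets <- c(0L, cumsum(n_obs_unit))
    for (s in seq_len(kept)) {
      for (j in seq_len(J)) {
        th <- theta_draws[s, j, ]
        if (model == "dual") {
          ar <- plogis(th[1]); ap <- plogis(th[2]); be <- min(exp(th[3]), beta_max)
        } else {
          ar <- plogis(th[1]); ap <- ar; be <- min(exp(th[2]), beta_max)
        }
        ii <- idx_list[[j]]
        log_lik[s, (offsets[j] + 1):offsets[j + 1]] <-
          qlearn_loglik_cpp(ii$a, ii$b, ii$chose_a, ii$outcome, ar, ap, be, q0)
      }
    }
    obs <- purrr::map_dfr(seq_len(J), function(j) {
      tibble::tibble(subject_id = units$subject_id[j],
                     condition = units$condition[j],
                     session = units$session[j],
                     trial = seq_len(n_obs_unit[j]))
    })

    # posterior means on the natural scale
    nat <- function(s, j) {
      th <- theta_draws[s, j, ]
      if (model == "dual") {
        c(plogis(th[1]), plogis(th[2]), min(exp(th[3]), beta_max))
      } else {
        c(plogis(th[1]), plogis(th[1]), min(exp(th[2]), beta_max))
      }
    }
    est_nat <- purrr::map(seq_len(J), function(j) {
      draws <- t(vapply(seq_len(kept), nat, numeric(3), j = j))
      colMeans(draws)
    })
    estimates <- purrr::map_dfr(seq_len(J), function(j) {
      e <- est_nat[[j]]
      pw <- colMeans(log_lik[, (offsets[j] + 1):offsets[j + 1], drop = FALSE])
      tibble::tibble(
        subject_id = units$subject_id[j], condition = units$condition[j],
        session = units$session[j],
        alpha_reward = e[1], alpha_punish = e[2], beta = e[3],
        nll = -sum(pw), n_trials = n_obs_unit[j],
        convergence = NA, flat_likelihood = NA,
        pointwise = list(pw)
      )
    })

    rhat <- vapply(seq_len(k), function(d) split_rhat(mu_draws[, d]), numeric(1))
    conv_warn <- any(rhat > 1.1, na.rm = TRUE)
    if (conv_warn) {
      warn(paste0("Hierarchical sampler convergence suspect: max split R-hat on group means = ",
                  signif(max(rhat, na.rm = TRUE), 3)))
    }
    estimates$convergence <- !conv_warn

    par_names <- if (model == "dual") {
      c("logit_alpha_reward", "logit_alpha_punish", "log_beta")
    } else {
      c("logit_alpha", "log_beta")
    }
    group <- tibble::tibble(
      parameter = par_names,
      mu_mean = colMeans(mu_draws),
      mu_sd = apply(mu_draws, 2, sd),
      sigma_mean = colMeans(sigma_draws),
      rhat = rhat
    )

    structure(
      list(estimates = estimates, model = model, method = "hierarchical",
           log_lik = log_lik, obs = obs, group = group,
           draws = list(theta = theta_draws, mu = mu_draws,
                        sigma = sigma_draws),
           diagnostics = list(
             rhat = rhat,
             accept_unit = acc_unit / iter,
             accept_sigma = acc_sigma / iter,
             convergence_warning = conv_warn
           )),
      class = "srl_fit"
    )
  })
}

# split R-hat of one chain: potential scale reduction between its halves
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 4) return(NA_real_)
  halves <- list(x[1:n], x[(length(x) - n + 1):length(x)])
  m <- 2
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  b <- n * var(means)
  w <- mean(vars)
  if (w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}
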