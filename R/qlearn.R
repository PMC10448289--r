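# Q-learning model of the selection-task training phase: update rule,
# softmax choice rule, sequential likelihood, and per-subject MLE.

#' Q-learning parameters
#'
#' Bundles the three parameters of the asymmetric Q-learning model: the
#' reward learning rate (weight given to positive prediction errors), the
#' punishment learning rate (weight given to negative prediction errors),
#' and the softmax inverse temperature. The single-learning-rate model is
#' the constraint `alpha_reward == alpha_punish`.
#'
#' @param alpha_reward,alpha_punish Learning rates in \[0, 1\].
#' @param beta Inverse temperature, >= 0 (0 = random choice).
#' @return A list of class `srl_qparams`.
#' @examples
#' q_params(0.3, 0.2, 5)
#' @export
q_params <- function(alpha_reward, alpha_punish = alpha_reward, beta = 5) {
  stopifnot(
    alpha_reward >= 0, alpha_reward <= 1,
    alpha_punish >= 0, alpha_punish <= 1,
    beta >= 0
  )
  structure(
    list(alpha_reward = alpha_reward, alpha_punish = alpha_punish, beta = beta),
    class = "srl_qparams"
  )
}

#' @export
print.srl_qparams <- function(x, ...) {
  cat(sprintf("<srl_qparams> alpha_reward=%.3f alpha_punish=%.3f beta=%.3f\n",
              x$alpha_reward, x$alpha_punish, x$beta))
  invisible(x)
}

#' Single Q-value update
#'
#' Applies one prediction-error update to the chosen face's expected value:
#' `q + alpha * (outcome - q)`, where `alpha` is the reward learning rate
#' for positive prediction errors and the punishment learning rate for
#' negative ones. With outcomes coded 0/1 a zero prediction error can only
#' occur at q exactly 0 or 1; there the valence of the outcome decides
#' (reward rate for 1, punishment rate for 0).
#'
#' @param q Current expected value(s) in \[0, 1\].
#' @param outcome Outcome(s) coded 1 (happy) or 0 (angry).
#' @param params An [q_params()] object.
#' @return Updated expected value(s), guaranteed to stay in \[0, 1\].
#' @examples
#' q_update(0.5, 1, q_params(0.3, 0.2))  # 0.65
#' @export
q_update <- function(q, outcome, params) {
  stopifnot(all(q >= 0 & q <= 1), all(outcome %in% c(0, 1)))
  pe <- outcome - q
  alpha <- ifelse(pe > 0, params$alpha_reward,
           ifelse(pe < 0, params$alpha_punish,
                  ifelse(outcome == 1, params$alpha_reward, params$alpha_punish)))
  q + alpha * pe
}

#' Softmax choice probability for a face pair
#'
#' Probability of choosing face a over face b under the logistic softmax
#' rule `p(a) = 1 / (1 + exp(-beta * (q_a - q_b)))`.
#'
#' @param q_a,q_b Expected values of the two faces.
#' @param beta Inverse temperature, >= 0.
#' @return Probability of choosing face a; `p(a) + p(b) = 1` by construction.
#' @examples
#' choice_prob(1, 0, 1)  # 0.731...
#' @export
choice_prob <- function(q_a, q_b, beta) {
  stopifnot(all(beta >= 0))
  plogis(beta * (q_a - q_b))
}

trials_to_indices <- function(trials) {
  faces <- srl_faces()
  list(
    a = match(trials$face_a, faces),
    b = match(trials$face_b, faces),
    chose_a = as.integer(trials$chosen == trials$face_a),
    outcome = as.integer(trials$outcome == "happy")
  )
}

#' Negative log-likelihood of a training sequence
#'
#' Sequentially replays one subject-session's time-ordered training trials,
#' computing the softmax log-probability of each observed choice under the
#' current expected values and then updating the chosen face's value with
#' the valence-appropriate learning rate. Expected values are initialized
#' at 0.5 for all six faces (the indifference point with outcomes coded
#' happy = 1, angry = 0).
#'
#' @param trials Train-phase trials for a single subject and session, in
#'   presentation order. A test-phase row is an error.
#' @param params An [q_params()] object.
#' @param q0 Initial expected values, a scalar or a vector of six.
#' @return A list with `nll` (the negative log-likelihood), `pointwise`
#'   (per-trial log-likelihoods, all <= 0, negated-summing to `nll`), and
#'   `n` (the number of trials).
#' @examples
#' \dontrun{
#' nll(one_subject_trials, q_params(0.3, 0.2, 5))
#' }
#' @export
nll <- function(trials, params, q0 = 0.5) {
  if (any(trials$phase != "train")) {
    abort("nll() models the training phase only; test-phase trials present",
          class = "srl_validation_error")
  }
  q0 <- rep_len(q0, length(srl_faces()))
  idx <- trials_to_indices(trials)
  pw <- qlearn_loglik_cpp(idx$a, idx$b, idx$chose_a, idx$outcome,
                          params$alpha_reward, params$alpha_punish,
                          params$beta, q0)
  list(nll = -sum(pw), pointwise = pw, n = length(pw))
}

# Negative log-likelihood on the unconstrained scale used by the optimizer
# and the hierarchical sampler: logit learning rates, log inverse
# temperature (capped at beta_max).
nll_transformed <- function(x, idx, model, beta_max, q0) {
  if (model == "dual") {
    ar <- plogis(x[1]); ap <- plogis(x[2]); beta <- exp(x[3])
  } else {
    ar <- plogis(x[1]); ap <- ar; beta <- exp(x[2])
  }
  if (beta > beta_max) return(1e10)
  -sum(qlearn_loglik_cpp(idx$a, idx$b, idx$chose_a, idx$outcome,
                         ar, ap, beta, q0))
}

#' Maximum-likelihood Q-learning fit for one subject-session
#'
#' Minimizes the training-phase negative log-likelihood on transformed
#' scales (logit for the learning rates, log for the inverse temperature,
#' capped at `beta_max`) with L-BFGS-B from `n_restarts` start points; the
#' best optimum is kept. A likelihood-ratio diagnostic against the
#' random-choice model (`beta = 0`) flags subjects whose data carry no
#' evidence of value-guided choice (`flat_likelihood`).
#'
#' @param trials Train-phase trials of a single subject-session, in order.
#' @param model `"dual"` (separate reward/punishment learning rates) or
#'   `"single"` (one shared rate, nested in the dual model).
#' @param n_restarts Number of optimizer starts (the first deterministic,
#'   the rest drawn from the seeded RNG).
#' @param seed Seed for the restart draws; identical data and seed give
#'   identical estimates.
#' @param beta_max Upper cap on the inverse temperature.
#' @return A one-row tibble with estimates, `nll`, `n_trials`,
#'   `convergence` and `flat_likelihood`, plus a `pointwise` list-column of
#'   per-trial log-likelihoods at the optimum.
#' @export
fit_mle <- function(trials, model = c("dual", "single"), n_restarts = 5,
                    seed = 1, beta_max = 20) {
  model <- match.arg(model)
  if (nrow(trials) < 30) {
    abort("fit_mle() requires at least 30 training trials",
          class = "srl_fit_error")
  }
  idx <- trials_to_indices(trials)
  q0 <- rep(0.5, length(srl_faces()))
  k <- if (model == "dual") 3L else 2L
  lower <- c(rep(-7, k - 1), log(1e-3))
  upper <- c(rep(7, k - 1), log(beta_max))

  starts <- matrix(NA_real_, n_restarts, k)
  starts[1, ] <- c(rep(qlogis(0.3), k - 1), log(3))
  if (n_restarts > 1) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    for (r in 2:n_restarts) {
      starts[r, ] <- c(qlogis(runif(k - 1, 0.05, 0.95)),
                       log(runif(1, 0.5, min(beta_max, 15))))
    }
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      optim(starts[r, ], nll_transformed, idx = idx, model = model,
            beta_max = beta_max, q0 = q0, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    abort("All optimizer restarts failed", class = "srl_fit_error")
  }

  x <- best$par
  if (model == "dual") {
    ar <- plogis(x[1]); ap <- plogis(x[2]); beta <- exp(x[3])
  } else {
    ar <- plogis(x[1]); ap <- ar; beta <- exp(x[2])
  }
  pw <- qlearn_loglik_cpp(idx$a, idx$b, idx$chose_a, idx$outcome,
                          ar, ap, beta, q0)
  n <- length(pw)
  # LR test vs. the random agent: nll under beta = 0 is n * log(2)
  flat <- (n * log(2) - best$value) < stats::qchisq(0.95, df = k) / 2
  tibble::tibble(
    alpha_reward = ar, alpha_punish = ap, beta = beta,
    nll = best$value, n_trials = n,
    convergence = best$convergence == 0,
    flat_likelihood = flat,
    pointwise = list(pw)
  )
}

#' Fit the Q-learning model across a cohort
#'
#' Fits each subject-session's training-phase choices independently (the
#' two sessions are treated as repeated measures downstream, not pooled
#' here). The maximum-likelihood path is deterministic and is the default;
#' [fit_hierarchical()] provides the partially pooled Bayesian alternative.
#'
#' @param trials A validated trial table (any mix of phases; only
#'   train-phase rows are modeled).
#' @param model `"dual"` or `"single"`.
#' @param method Currently `"mle"`; use [fit_hierarchical()] directly for
#'   the Bayesian fit.
#' @param n_restarts,seed,beta_max Passed to [fit_mle()]; per-subject seeds
#'   are derived from `seed` so any subject is refittable in isolation.
#' @return An object of class `srl_fit` with an `estimates` tibble (one row
#'   per subject x session) carrying a `pointwise` list-column of per-trial
#'   log-likelihoods. Use [tidy()] / [glance()] to extract summaries.
#' @examples
#' \dontrun{
#' study <- simulate_study(study_config(task = list(n_cbmi = 3, n_ema = 3)), seed = 1)
#' fit <- fit_rl(study$trials, model = "dual")
#' tidy(fit)
#' }
#' @export
fit_rl <- function(trials, model = c("dual", "single"),
                   method = "mle", n_restarts = 5, seed = 1, beta_max = 20) {
  model <- match.arg(model)
  stopifnot(method == "mle")
  validate_trials(trials)
  train <- dplyr::filter(trials, .data$phase == "train")
  if (nrow(train) == 0) abort("No training trials to fit", class = "srl_fit_error")

  groups <- train |>
    dplyr::distinct(.data$subject_id, .data$session) |>
    dplyr::arrange(.data$subject_id, .data$session)
  sub_seeds <- derive_seeds(seed, nrow(groups))

  estimates <- purrr::map2_dfr(
    seq_len(nrow(groups)), sub_seeds,
    function(i, s) {
      g <- groups[i, ]
      tr <- train |>
        dplyr::filter(.data$subject_id == g$subject_id,
                      .data$session == g$session) |>
        dplyr::arrange(.data$trial_index)
      est <- fit_mle(tr, model = model, n_restarts = n_restarts,
                     seed = s, beta_max = beta_max)
      cond <- if ("condition" %in% names(tr)) tr$condition[1] else NA_character_
      dplyr::bind_cols(
        tibble::tibble(subject_id = g$subject_id, condition = cond,
                       session = g$session),
        est
      )
    }
  )

  structure(
    list(estimates = estimates, model = model, method = method,
         log_lik = NULL),
    class = "srl_fit"
  )
}

#' @export
print.srl_fit <- function(x, ...) {
  cat("<srl_fit> model=", x$model, " method=", x$method,
      " (", nrow(x$estimates), " subject-sessions)\n", sep = "")
  invisible(x)
}

#' @describeIn fit_rl Per-subject-session parameter estimates as a tibble
#'   (without the pointwise list-column).
#' @param x An `srl_fit` object.
#' @export
tidy.srl_fit <- function(x, ...) {
  dplyr::select(x$estimates, -dplyr::any_of("pointwise"))
}

#' @describeIn fit_rl One-row model-level summary: total negative
#'   log-likelihood, number of parameters, AIC, subjects and trials.
#' @export
glance.srl_fit <- function(x, ...) {
  k <- if (x$model == "dual") 3L else 2L
  est <- x$estimates
  tibble::tibble(
    model = x$model, method = x$method,
    n_subject_sessions = nrow(est),
    n_trials = sum(est$n_trials),
    nll = sum(est$nll),
    n_parameters = k * nrow(est),
    aic = 2 * k * nrow(est) + 2 * sum(est$nll)
  )
}

#' Pointwise log-likelihood matrix of a fit
#'
#' Returns the per-trial log-likelihoods of an [fit_rl()] or
#' [fit_hierarchical()] result as a draws x observations matrix (a single
#' pseudo-draw at the optimum for MLE fits), together with the observation
#' bookkeeping needed to group trials by condition and session.
#'
#' @param fit An `srl_fit` object.
#' @return A list with `log_lik` (matrix, draws x observations) and `obs`
#'   (tibble with `subject_id`, `condition`, `session` per observation).
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "srl_fit"))
  if (!is.null(fit$log_lik)) {
    return(list(log_lik = fit$log_lik, obs = fit$obs))
  }
  est <- fit$estimates
  obs <- purrr::map_dfr(seq_len(nrow(est)), function(i) {
    tibble::tibble(
      subject_id = est$subject_id[i],
      condition = est$condition[i],
      session = est$session[i],
      trial = seq_along(est$pointwise[[i]])
    )
  })
  list(
    log_lik = matrix(unlist(est$pointwise), nrow = 1),
    obs = obs
  )
}
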