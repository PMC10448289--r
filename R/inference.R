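# Mixed-effects inference stage: linear mixed models on learning rates and
# update weights, trial-level logistic mixed model on testing-phase
# accuracy, Tukey-adjusted marginal-mean contrasts, and standardized
# effect sizes.

# +/- 1/2 effects coding with fixed, documented level orientations so that
# the intercept is the grand mean and interaction signs line up with the
# synthetic generator's conventions: session 2, CBM-I, positive PE, poor
# items and choose-reward trials sit on the + side. Unknown two-level
# variables are coded alphabetically (first level -1/2).
effect_levels <- list(
  session = c("1", "2"),
  condition = c("EMA-only", "CBM-I"),
  pe_valence = c("negative", "positive"),
  valence = c("good", "poor"),
  label = c("avoid_punish", "choose_reward")
)

#' Apply +/- 1/2 effects coding to model factors
#'
#' Converts the named variables to factors with sum-to-zero contrasts
#' scaled to +/- 1/2, so that a fixed-effect estimate is the difference
#' between the two cell means and the intercept is the grand mean.
#' Orientation is fixed for the package's standard factors (session 2,
#' CBM-I, positive PE valence, poor items, choose-reward trials on the
#' positive side); other two-level variables are oriented alphabetically.
#'
#' @param data A data frame.
#' @param vars Variables to code; defaults to every standard factor present.
#' @return The data frame with coded factor columns.
#' @export
code_effects <- function(data, vars = intersect(names(effect_levels), names(data))) {
  for (v in vars) {
    x <- as.character(data[[v]])
    levels <- effect_levels[[v]] %||% sort(unique(x))
    stopifnot(all(x %in% levels))
    f <- factor(x, levels = levels)
    k <- nlevels(f)
    if (k == 2) {
      stats::contrasts(f) <- matrix(c(-0.5, 0.5), 2, 1,
                                    dimnames = list(levels, levels[2]))
    } else {
      stats::contrasts(f) <- stats::contr.sum(k) / 2
    }
    data[[v]] <- f
  }
  data
}

nakagawa_r2 <- function(fit, sigma2, tau00) {
  X <- stats::model.matrix(fit)
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
  total <- var_f + tau00 + sigma2
  list(marginal = var_f / total, conditional = (var_f + tau00) / total)
}

extract_ranef_block <- function(fit, sigma2) {
  vc <- lme4::VarCorr(fit)
  tau00 <- if (length(vc) > 0) as.numeric(vc[[1]][1, 1]) else 0
  r2 <- nakagawa_r2(fit, sigma2, tau00)
  list(
    sigma2 = sigma2, tau00 = tau00,
    icc = tau00 / (tau00 + sigma2),
    n_obs = stats::nobs(fit),
    n_groups = unname(lme4::ngrps(fit)[1]),
    r2_marginal = r2$marginal,
    r2_conditional = r2$conditional
  )
}

#' Linear mixed model with effects-coded factors
#'
#' Fits a linear mixed model (REML, via lmerTest for Satterthwaite degrees
#' of freedom) after applying +/- 1/2 effects coding to the standard
#' factors, and extracts a publication-style summary: fixed effects with
#' 95% CIs, t statistics on approximate df, and a random-effects block
#' (residual variance, random-intercept variance, ICC, marginal and
#' conditional R-squared). A singular random-effects fit is flagged in the
#' result, not silently dropped.
#'
#' @param data A data frame with complete cases for all model variables.
#' @param formula A lmer-style formula, e.g.
#'   `learning_rate ~ session * condition * pe_valence + (1 | subject_id)`.
#' @return An object of class `srl_lmm`: the underlying fit plus `fixed`
#'   (tibble) and `ranef` (list) summaries. Use [tidy()] / [glance()].
#' @export
fit_lmm <- function(data, formula) {
  data <- code_effects(as.data.frame(data))
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("Model variable(s) absent from data: ",
                 paste(missing_vars, collapse = ", ")))
  }
  data <- data[stats::complete.cases(data[, vars]), , drop = FALSE]
  fit <- suppressMessages(lmerTest::lmer(formula, data = data))
  singular <- lme4::isSingular(fit)
  if (singular) warn("Random-effects fit is singular (variance at boundary)")
  sm <- as.data.frame(summary(fit)$coefficients)
  ci <- suppressMessages(stats::confint(fit, parm = "beta_", method = "Wald"))
  fixed <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    conf.low = ci[, 1],
    conf.high = ci[, 2],
    statistic = sm[, "t value"],
    df = sm[, "df"],
    p.value = sm[, "Pr(>|t|)"]
  )
  ranef <- extract_ranef_block(fit, sigma2 = stats::sigma(fit)^2)
  structure(
    list(fit = fit, fixed = fixed, ranef = ranef, formula = formula,
         singular = singular, link = "identity"),
    class = c("srl_lmm", "srl_model")
  )
}

#' Trial-level logistic mixed model on testing-phase accuracy
#'
#' Fits a binomial GLMM (logit link, Laplace approximation) to trial-level
#' correct/incorrect records, with the same effects coding as [fit_lmm()],
#' and summarizes fixed effects as odds ratios with Wald CIs and z tests.
#' On the latent scale the residual variance is fixed at pi^2 / 3, which is
#' what the ICC and R-squared entries use. Complete separation or a
#' singular fit raises a carried warning.
#'
#' @param data A data frame with a binary (0/1 or logical) response.
#' @param formula A glmer-style formula, e.g.
#'   `correct ~ session * condition * label + (1 | subject_id)`.
#' @return An object of class `srl_glmm` with `fixed` (odds-ratio tibble)
#'   and `ranef` summaries.
#' @export
fit_glmm <- function(data, formula) {
  data <- code_effects(as.data.frame(data))
  vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[, vars]), , drop = FALSE]
  response <- data[[vars[1]]]
  if (!all(response %in% c(0, 1, TRUE, FALSE))) {
    abort("fit_glmm() needs a binary response")
  }
  fit <- suppressMessages(
    lme4::glmer(formula, data = data, family = stats::binomial())
  )
  singular <- lme4::isSingular(fit)
  if (singular) warn("Random-effects fit is singular (variance at boundary)")
  sm <- as.data.frame(summary(fit)$coefficients)
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  fixed <- tibble::tibble(
    term = rownames(sm),
    estimate = est,
    std.error = se,
    odds.ratio = exp(est),
    conf.low = exp(est - qnorm(0.975) * se),
    conf.high = exp(est + qnorm(0.975) * se),
    statistic = sm[, "z value"],
    p.value = sm[, "Pr(>|z|)"]
  )
  sigma2 <- pi^2 / 3  # latent-scale residual variance of the logit link
  ranef <- extract_ranef_block(fit, sigma2 = sigma2)
  structure(
    list(fit = fit, fixed = fixed, ranef = ranef, formula = formula,
         singular = singular, link = "logit"),
    class = c("srl_glmm", "srl_model")
  )
}

#' @export
print.srl_model <- function(x, ...) {
  cat("<", class(x)[1], "> ", deparse(x$formula), "\n", sep = "")
  print(x$fixed)
  cat(sprintf("sigma2 = %.3f, tau00 = %.3f, ICC = %.2f, R2m = %.3f, R2c = %.3f%s\n",
              x$ranef$sigma2, x$ranef$tau00, x$ranef$icc,
              x$ranef$r2_marginal, x$ranef$r2_conditional,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' @describeIn fit_lmm Fixed-effect summary tibble.
#' @param x An `srl_lmm` or `srl_glmm` object.
#' @export
tidy.srl_model <- function(x, ...) x$fixed

#' @describeIn fit_lmm One-row random-effects / fit summary.
#' @export
glance.srl_model <- function(x, ...) {
  tibble::as_tibble(x$ranef) |>
    dplyr::mutate(singular = x$singular, link = x$link, .before = 1)
}

#' Tukey-adjusted pairwise contrasts of estimated marginal means
#'
#' Computes estimated marginal means for the requested factor and pairwise
#' differences within each `by` slice, family-wise adjusted (Tukey by
#' default). For logit-link models the contrasts are reported on the logit
#' scale. Satterthwaite degrees of freedom are used for linear mixed
#' models; z tests for GLMMs.
#'
#' @param model An [fit_lmm()] or [fit_glmm()] result.
#' @param specs Name of the factor whose levels are compared.
#' @param by Optional faceting factor(s) within which comparisons are made.
#' @param adjust Multiplicity adjustment (default `"tukey"`).
#' @return A tibble of contrasts: estimate, SE, df, statistic, adjusted
#'   p-value, plus the estimated marginal means as the `"emmeans"`
#'   attribute.
#' @export
emm_contrasts <- function(model, specs, by = NULL, adjust = "tukey") {
  stopifnot(inherits(model, "srl_model"))
  all_factors <- c(specs, by)
  present <- all_factors %in% all.vars(model$formula)
  if (!all(present)) {
    abort(paste0("Factor(s) not in model: ",
                 paste(all_factors[!present], collapse = ", ")))
  }
  em <- emmeans::emmeans(model$fit, specs = specs, by = by,
                         lmer.df = "satterthwaite")
  prs <- summary(emmeans::contrast(em, method = "pairwise", adjust = adjust),
                 infer = TRUE)
  prs <- as.data.frame(prs)
  stat_col <- intersect(c("t.ratio", "z.ratio"), names(prs))
  out <- tibble::as_tibble(prs) |>
    dplyr::rename(std.error = "SE", p.value = "p.value") |>
    dplyr::mutate(statistic = prs[[stat_col]])
  if (!"df" %in% names(out)) out$df <- NA_real_
  attr(out, "emmeans") <- tibble::as_tibble(as.data.frame(em))
  attr(out, "adjust") <- adjust
  out
}

#' Standardized effect size for marginal-mean contrasts
#'
#' Converts contrast estimates to a Cohen's d by dividing by the total
#' random SD of the model, `sqrt(tau00 + sigma2)` (random-intercept
#' variance plus residual variance; for logit models the latent-scale
#' residual pi^2 / 3). The sign of d matches the sign of the estimate.
#'
#' @param contrasts A tibble from [emm_contrasts()].
#' @param model The model the contrasts came from.
#' @return The contrast tibble with a `cohens_d` column appended.
#' @export
effect_size <- function(contrasts, model) {
  stopifnot(inherits(model, "srl_model"))
  total_var <- model$ranef$tau00 + model$ranef$sigma2
  if (total_var <= 0) {
    abort("Total random variance is zero; effect size undefined")
  }
  dplyr::mutate(contrasts, cohens_d = .data$estimate / sqrt(total_var))
}
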