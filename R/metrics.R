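# Testing-phase accuracy metrics and speech-task update-weight estimation.

intermediate_faces <- function() c("p70", "p60", "p40", "p30")

#' Label testing-phase trials as choose-reward or avoid-punish
#'
#' Classifies each recombined test pair: `choose_reward` when the most
#' rewarding face (`p80`) is paired with an intermediate face (70/60/40/30),
#' `avoid_punish` when the most punishing face (`p20`) is paired with an
#' intermediate face, and `excluded` otherwise (the p80-vs-p20 pair and the
#' intermediate-only pairs, which belong to neither metric). A trial is
#' `correct` when the face with the higher reward probability was chosen.
#'
#' @param trials Test-phase trials (a train-phase row is an error).
#' @return The input tibble with `label` and `correct` columns appended.
#' @export
label_test_trials <- function(trials) {
  if (any(trials$phase != "test")) {
    abort("label_test_trials() applies to test-phase trials only",
          class = "srl_validation_error")
  }
  has <- function(face) trials$face_a == face | trials$face_b == face
  with_intermediate <- trials$face_a %in% intermediate_faces() |
    trials$face_b %in% intermediate_faces()
  label <- dplyr::case_when(
    has("p80") & with_intermediate ~ "choose_reward",
    has("p20") & with_intermediate ~ "avoid_punish",
    TRUE ~ "excluded"
  )
  better <- ifelse(face_prob(trials$face_a) >= face_prob(trials$face_b),
                   trials$face_a, trials$face_b)
  dplyr::mutate(trials, label = label, correct = .data$chosen == better)
}

#' Testing-phase accuracy per subject, session and trial type
#'
#' Computes the proportion of correct choices in the two eligible trial
#' types (choose-reward and avoid-punish), per subject and session.
#' Excluded pairs do not contribute. Cells with zero eligible trials are
#' kept with `n_trials = 0` and a missing proportion.
#'
#' @param trials A trial table; only test-phase rows are used.
#' @return A tibble with `subject_id`, `condition` (if present), `session`,
#'   `label`, `n_trials`, `n_correct` and `accuracy`. Trial-level binary
#'   records for the GLMM stage come from [label_test_trials()].
#' @export
accuracy_table <- function(trials) {
  test <- dplyr::filter(trials, .data$phase == "test")
  if (nrow(test) == 0) {
    abort("No test-phase trials present", class = "srl_validation_error")
  }
  labeled <- label_test_trials(test) |>
    dplyr::filter(.data$label != "excluded")
  keys <- intersect(c("subject_id", "condition", "session"), names(labeled))
  labeled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "label")))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      .groups = "drop"
    ) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(keys)),
      label = c("choose_reward", "avoid_punish"),
      fill = list(n_trials = 0L, n_correct = 0L)
    ) |>
    dplyr::mutate(accuracy = ifelse(.data$n_trials > 0,
                                    .data$n_correct / .data$n_trials,
                                    NA_real_))
}

#' Classify the prediction-error valence of a speech item
#'
#' For items describing good speech performance, the prediction error is
#' positive when the feedback rating exceeds the pre-speech self-rating;
#' for items describing poor performance the rule is reversed (lower
#' feedback on a feared behavior is good news). Feedback equal to the
#' pre-rating is a zero prediction error.
#'
#' @param valence Item valence, `"good"` or `"poor"` (vectorized).
#' @param pre_rating,feedback_rating Ratings in \[0, 100\].
#' @return Character vector: `"positive"`, `"negative"` or `"zero"`.
#' @examples
#' classify_pe("good", 40, 70)  # positive
#' classify_pe("poor", 60, 30)  # positive (reversed scoring)
#' @export
classify_pe <- function(valence, pre_rating, feedback_rating) {
  stopifnot(all(valence %in% c("good", "poor")))
  raw <- sign(feedback_rating - pre_rating)
  signed <- ifelse(valence == "poor", -raw, raw)
  dplyr::case_when(
    signed > 0 ~ "positive",
    signed < 0 ~ "negative",
    TRUE ~ "zero"
  )
}

#' Single-shot update weight of a speech item
#'
#' The update weight is the one-instance analogue of a learning rate:
#' `w = (post - pre) / (feedback - pre)`, i.e. the fraction of the distance
#' toward the feedback that the post-speech expectancy moved. It is
#' undefined (returned as `NA`) when the feedback equals the pre-rating;
#' such zero-prediction-error items are excluded upstream. Weights are not
#' clipped: overshooting (`w > 1`) and counter-updating (`w < 0`) are
#' representable and are what influence screening may later remove.
#'
#' @param pre_rating,feedback_rating,post_rating Item ratings (vectorized).
#' @return Numeric vector of update weights.
#' @examples
#' item_weight(40, 80, 60)  # 0.5
#' @export
item_weight <- function(pre_rating, feedback_rating, post_rating) {
  denom <- feedback_rating - pre_rating
  ifelse(denom == 0, NA_real_, (post_rating - pre_rating) / denom)
}

scheme_categories <- function(scheme) {
  switch(scheme,
    one = "all",
    pe_valence = c("negative", "positive"),
    item_valence = c("good", "poor"),
    four = c("negative_good", "negative_poor", "positive_good", "positive_poor")
  )
}

#' Aggregate item-level update weights per subject
#'
#' Computes per-item update weights, drops zero-prediction-error items
#' (recorded with a reason), assigns each retained item to a category under
#' the requested aggregation scheme, and aggregates within category.
#' The four schemes mirror the candidate update-weight models: one weight
#' over all 20 items, two weights split by PE valence, two split by item
#' valence, and four weights for each PE x item valence cell.
#'
#' @param speech A validated speech-item table (one or many subjects).
#' @param scheme `"one"`, `"pe_valence"`, `"item_valence"` or `"four"`.
#' @param estimator `"mean"` (arithmetic mean of item weights, the default)
#'   or `"regression"` (regression of `post - pre` on `feedback - pre`
#'   through the origin within category).
#' @return A tibble with one row per subject x category: `weight`,
#'   `n_items`, and the `scheme`; categories with no retained items are kept
#'   with `n_items = 0` and a missing weight. The excluded items (with
#'   reasons) are attached as the `"excluded"` attribute.
#' @export
aggregate_weights <- function(speech,
                              scheme = c("pe_valence", "item_valence",
                                         "one", "four"),
                              estimator = c("mean", "regression")) {
  scheme <- match.arg(scheme)
  estimator <- match.arg(estimator)
  validate_speech(speech)
  keys <- intersect(c("subject_id", "condition"), names(speech))

  items <- speech |>
    dplyr::mutate(
      pe_valence = classify_pe(.data$valence, .data$pre_rating,
                               .data$feedback_rating),
      weight_item = item_weight(.data$pre_rating, .data$feedback_rating,
                                .data$post_rating)
    )
  excluded <- items |>
    dplyr::filter(.data$pe_valence == "zero") |>
    dplyr::select(dplyr::all_of(c(keys, "item_id"))) |>
    dplyr::mutate(reason = "zero prediction error: update weight undefined")
  retained <- items |>
    dplyr::filter(.data$pe_valence != "zero") |>
    dplyr::mutate(category = switch(scheme,
      one = "all",
      pe_valence = .data$pe_valence,
      item_valence = .data$valence,
      four = paste(.data$pe_valence, .data$valence, sep = "_")
    ))

  out <- retained |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "category")))) |>
    dplyr::summarise(
      weight = if (estimator == "mean") {
        mean(.data$weight_item)
      } else {
        sum((.data$post_rating - .data$pre_rating) *
              (.data$feedback_rating - .data$pre_rating)) /
          sum((.data$feedback_rating - .data$pre_rating)^2)
      },
      n_items = dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(keys)),
      category = scheme_categories(scheme),
      fill = list(n_items = 0L)
    ) |>
    dplyr::mutate(scheme = scheme, .after = dplyr::all_of(keys))
  attr(out, "excluded") <- excluded
  out
}

#' Screen influential outliers from a weight table
#'
#' Case-deletion influence screening for the mixed-model stage: the
#' specified model is fit to the full table, then refit with each
#' observation deleted in turn, and the influence of observation i is the
#' mean squared standardized change in the fixed effects,
#' `D_i = mean_j ((b_j - b_j(-i)) / SE_j)^2` — a Cook's-distance analogue
#' on the fixed effects. Observations with `D_i` above the threshold
#' (default `4 / n`) are removed in a single pass.
#'
#' @param data The weight table (one row per subject x category).
#' @param formula Mixed-model formula defining the fixed effects whose
#'   stability is screened; defaults to
#'   `weight ~ category * condition + (1 | subject_id)`. If the random
#'   effect cannot be fit, an ordinary linear model on the fixed effects is
#'   used instead.
#' @param threshold Influence threshold; `NULL` or `NA` means `4 / n`.
#' @return A list of class `srl_screen` with `retained`, `removed` (with an
#'   `influence` column), `threshold` and `n_removed`.
#' @export
screen_outliers <- function(data,
                            formula = weight ~ category * condition +
                              (1 | subject_id),
                            threshold = NULL) {
  data <- dplyr::filter(data, !is.na(.data$weight))
  n <- nrow(data)
  if (is.null(threshold) || is.na(threshold)) threshold <- 4 / n
  for (v in all.vars(formula)) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
  }

  fit_once <- function(d) {
    has_ranef <- length(lme4::findbars(formula)) > 0
    if (has_ranef) {
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(formula, data = d,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore"))
        )),
        error = function(e) NULL
      )
      if (!is.null(fit)) return(fit)
    }
    fixed <- lme4::nobars(formula)
    stats::lm(fixed, data = d)
  }

  full <- fit_once(data)
  b <- fixed_coefs(full)
  se <- fixed_ses(full)

  influence <- vapply(seq_len(n), function(i) {
    fit_i <- tryCatch(fit_once(data[-i, ]), error = function(e) NULL)
    if (is.null(fit_i)) return(NA_real_)
    b_i <- fixed_coefs(fit_i)
    common <- intersect(names(b), names(b_i))
    mean(((b[common] - b_i[common]) / se[common])^2)
  }, numeric(1))

  flag <- !is.na(influence) & influence > threshold
  structure(
    list(
      retained = data[!flag, , drop = FALSE],
      removed = dplyr::mutate(data[flag, , drop = FALSE],
                              influence = influence[flag]),
      influence = influence,
      threshold = threshold,
      n_removed = sum(flag)
    ),
    class = "srl_screen"
  )
}

fixed_coefs <- function(fit) {
  if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
}

fixed_ses <- function(fit) {
  v <- as.matrix(vcov(fit))
  setNames(sqrt(diag(v)), names(fixed_coefs(fit)))
}

#' @export
print.srl_screen <- function(x, ...) {
  cat("<srl_screen> removed ", x$n_removed, " of ",
      nrow(x$retained) + x$n_removed,
      " observations (threshold ", signif(x$threshold, 3), ")\n", sep = "")
  invisible(x)
}
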