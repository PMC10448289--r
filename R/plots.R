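# ggplot2 figures for the main result types.

#' Plot learning rates by session, condition and PE valence
#'
#' Mean estimated (or true) learning rate with standard-error bars, split
#' by session on the x axis, condition as color and PE valence as facets —
#' the layout used to read session-by-condition and session-by-valence
#' interactions.
#'
#' @param rates A tibble with `session`, `condition`, `pe_valence` and a
#'   rate column (`learning_rate`), e.g. from [rates_from_fit()] or
#'   [simulate_rates()].
#' @return A ggplot object.
#' @export
plot_learning_rates <- function(rates) {
  summ <- rates |>
    dplyr::group_by(.data$session, .data$condition, .data$pe_valence) |>
    dplyr::summarise(
      mean = mean(.data$learning_rate),
      se = stats::sd(.data$learning_rate) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$session), y = .data$mean,
                                     color = .data$condition,
                                     group = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1,
                           position = ggplot2::position_dodge(0.2)) +
    ggplot2::facet_wrap(~pe_valence) +
    ggplot2::labs(x = "Session", y = "Learning rate", color = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot testing-phase accuracy by session, condition and trial type
#'
#' @param accuracy An [accuracy_table()] tibble.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy) {
  summ <- accuracy |>
    dplyr::filter(!is.na(.data$accuracy)) |>
    dplyr::group_by(.data$session, .data$condition, .data$label) |>
    dplyr::summarise(
      mean = mean(.data$accuracy),
      se = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = factor(.data$session), y = .data$mean,
                                     color = .data$condition,
                                     group = .data$condition)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.1,
                           position = ggplot2::position_dodge(0.2)) +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Session", y = "Proportion correct", color = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot update weights by category and condition
#'
#' @param weights An [aggregate_weights()] tibble.
#' @return A ggplot object.
#' @export
plot_update_weights <- function(weights) {
  summ <- weights |>
    dplyr::filter(!is.na(.data$weight)) |>
    dplyr::group_by(.data$condition, .data$category) |>
    dplyr::summarise(
      mean = mean(.data$weight),
      se = stats::sd(.data$weight) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$category, y = .data$mean,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2,
                           position = ggplot2::position_dodge(0.8)) +
    ggplot2::labs(x = "Category", y = "Update weight", fill = "Condition") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_rl Scatter of reward vs punishment learning-rate
#'   estimates, colored by session.
#' @param object An `srl_fit` object.
#' @export
autoplot.srl_fit <- function(object, ...) {
  est <- tidy(object)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$alpha_reward,
                                    y = .data$alpha_punish,
                                    color = factor(.data$session))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Reward learning rate", y = "Punishment learning rate",
                  color = "Session") +
    ggplot2::theme_minimal()
}

#' Learning rates in long format from a fitted model
#'
#' Reshapes an [fit_rl()] result into the subject x session x PE-valence
#' long table the mixed-model stage consumes (`pe_valence = "positive"`
#' rows carry the reward learning rate, `"negative"` rows the punishment
#' rate).
#'
#' @param fit An `srl_fit` object.
#' @return A tibble with `subject_id`, `condition`, `session`,
#'   `pe_valence`, `learning_rate` and `beta`.
#' @export
rates_from_fit <- function(fit) {
  tidy(fit) |>
    dplyr::select(dplyr::all_of(c("subject_id", "condition", "session",
                                  "alpha_reward", "alpha_punish", "beta"))) |>
    tidyr::pivot_longer(c("alpha_reward", "alpha_punish"),
                        names_to = "pe_valence", values_to = "learning_rate") |>
    dplyr::mutate(pe_valence = ifelse(.data$pe_valence == "alpha_reward",
                                      "positive", "negative"))
}
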