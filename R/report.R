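# Human-readable run report assembling the pipeline's outputs.

format_fixed_table <- function(model) {
  f <- model$fixed
  if (model$link == "logit") {
    header <- "| Predictor | OR (95% CI) | z | p |"
    sep <- "|---|---|---|---|"
    rows <- sprintf("| %s | %.2f (%.2f-%.2f) | %.2f | %.3g |",
                    f$term, f$odds.ratio, f$conf.low, f$conf.high,
                    f$statistic, f$p.value)
  } else {
    header <- "| Predictor | Estimate (95% CI) | t (df) | p |"
    sep <- "|---|---|---|---|"
    rows <- sprintf("| %s | %.3f (%.3f to %.3f) | %.2f (%.1f) | %.3g |",
                    f$term, f$estimate, f$conf.low, f$conf.high,
                    f$statistic, f$df, f$p.value)
  }
  r <- model$ranef
  c(header, sep, rows,
    sprintf("\nRandom effects: sigma^2 = %.3f, tau00 = %.3f, ICC = %.2f, observations = %d, marginal R^2 = %.3f, conditional R^2 = %.3f%s",
            r$sigma2, r$tau00, r$icc, r$n_obs, r$r2_marginal,
            r$r2_conditional,
            if (model$singular) " (singular fit)" else ""))
}

#' Assemble a run report
#'
#' Builds a markdown report from whichever pipeline outputs are supplied:
#' the learning-rate mixed model, the trial-level accuracy GLMM, the
#' update-weight models per scheme, the single-vs-dual model comparison,
#' and any marginal-mean contrast tables. Missing stages are flagged
#' explicitly rather than dropped, and the seed and configuration are
#' embedded so the report identifies its run. Reruns with the same inputs
#' produce identical text.
#'
#' @param results A named list with any of: `study` (an `srl_study`),
#'   `rate_model`, `accuracy_model` (fitted models), `weight_models`
#'   (named list of fitted models), `model_comparison` (tibble from
#'   [compare_fits()]), `contrasts` (named list of tibbles), `seed`,
#'   `config`.
#' @param path Optional file to write the report to.
#' @return The report lines, invisibly (a character vector).
#' @export
report <- function(results, path = NULL) {
  stopifnot(is.list(results))
  lines <- c("# Social reinforcement learning analysis report", "")
  if (!is.null(results$seed)) {
    lines <- c(lines, paste0("Master seed: ", results$seed))
  }
  if (!is.null(results$config)) {
    lines <- c(lines, "", "```yaml",
               strsplit(yaml::as.yaml(unclass(results$config)), "\n")[[1]],
               "```")
  }
  if (!is.null(results$study)) {
    s <- results$study
    lines <- c(lines, "", "## Synthetic cohort",
               sprintf("%d subjects (%d CBM-I, %d EMA-only); %d trials; %d speech items.",
                       nrow(s$design), sum(s$design$condition == "CBM-I"),
                       sum(s$design$condition == "EMA-only"),
                       nrow(s$trials), nrow(s$speech)))
  }

  section <- function(lines, title, content) {
    c(lines, "", paste0("## ", title), "",
      if (is.null(content)) "*Stage missing: not supplied to report().*" else content)
  }
  lines <- section(lines, "Learning rates (training phase): mixed model",
                   if (!is.null(results$rate_model))
                     format_fixed_table(results$rate_model))
  lines <- section(lines, "Testing-phase accuracy: trial-level GLMM",
                   if (!is.null(results$accuracy_model))
                     format_fixed_table(results$accuracy_model))
  if (!is.null(results$weight_models)) {
    for (nm in names(results$weight_models)) {
      lines <- section(lines, paste0("Update weights (", nm, " scheme)"),
                       format_fixed_table(results$weight_models[[nm]]))
    }
  } else {
    lines <- section(lines, "Update weights", NULL)
  }
  if (!is.null(results$model_comparison)) {
    mc <- results$model_comparison
    lines <- c(lines, "", "## Model comparison (single vs dual learning rate)", "",
               paste0("| ", paste(names(mc), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(mc)), collapse = "|"), "|"),
               apply(mc, 1, function(r) paste0("| ", paste(format(r, digits = 4), collapse = " | "), " |")))
  }
  if (!is.null(results$contrasts)) {
    for (nm in names(results$contrasts)) {
      ct <- results$contrasts[[nm]]
      lines <- c(lines, "", paste0("## Contrasts: ", nm), "",
                 sprintf("- %s%s: estimate %.3f (SE %.3f), stat %.2f, adj. p = %.3g%s",
                         ct$contrast,
                         if ("cohens_d" %in% names(ct)) "" else "",
                         ct$estimate, ct$std.error, ct$statistic, ct$p.value,
                         if ("cohens_d" %in% names(ct))
                           sprintf(", d = %.2f", ct$cohens_d) else ""))
    }
  }
  lines <- c(lines, "", "---", "Generated by socialrl::report().")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
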