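test_that("effects coding gives +/- 1/2 contrasts with documented orientation", {
  d <- tibble::tibble(
    session = c(1L, 2L), condition = c("CBM-I", "EMA-only"),
    pe_valence = c("negative", "positive")
  )
  coded <- code_effects(d)
  expect_equal(unname(contrasts(coded$session)[, 1]), c(-0.5, 0.5))
  expect_equal(levels(coded$condition), c("EMA-only", "CBM-I"))
  expect_equal(unname(contrasts(coded$condition)["CBM-I", 1]), 0.5)
  expect_equal(unname(contrasts(coded$pe_valence)["positive", 1]), 0.5)
})

test_that("the learning-rate mixed model recovers a planted interaction", {
  design <- make_design(53, 53, seed = 2)
  effects <- list(session = 0.02, condition = 0, valence = 0.03,
                  session_condition = -0.06, session_valence = 0,
                  condition_valence = 0, session_condition_valence = 0)
  rates <- simulate_rates(
    design,
    rates = list(mean_alpha = 0.23, sd_subject = 0.04, sd_cell = 0.09,
                 effects = effects, clip = c(0.02, 0.98)),
    seed = 31
  )
  m <- fit_lmm(rates,
               learning_rate ~ session * condition * pe_valence +
                 (1 | subject_id))
  fx <- tidy(m)
  expect_equal(nrow(fx), 8L)
  # intercept is the grand mean under effects coding
  expect_equal(fx$estimate[fx$term == "(Intercept)"],
               mean(rates$learning_rate), tolerance = 0.01)
  # planted session x condition interaction recovered within 2 SE
  term <- fx[fx$term == "session2:conditionCBM-I", ]
  expect_lt(abs(term$estimate - (-0.06)), 2 * term$std.error)
  # planted session main effect recovered within 2 SE
  ses <- fx[fx$term == "session2", ]
  expect_lt(abs(ses$estimate - 0.02), 2 * ses$std.error)
  # Satterthwaite df are non-integer and within the data's range
  expect_true(all(fx$df > 2 & fx$df < nrow(rates)))
  g <- glance(m)
  expect_gt(g$icc, 0)
  expect_gte(g$r2_conditional, g$r2_marginal)
})

test_that("degenerate random-effects structure is flagged, not hidden", {
  # identical between-subject means force the intercept variance to the
  # boundary: a deterministic singular fit
  d <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:40), each = 2),
    condition = rep(rep(c("CBM-I", "EMA-only"), each = 2), 20),
    learning_rate = rep(c(0.2, 0.3), 40)
  )
  expect_warning(
    m <- fit_lmm(d, learning_rate ~ condition + (1 | subject_id)),
    "singular"
  )
  expect_true(m$singular)
})

test_that("the accuracy GLMM matches observed odds and recovers effects", {
  set.seed(11)
  n_subj <- 60
  n_trial <- 40
  d <- tidyr::expand_grid(subject_id = sprintf("S%03d", 1:n_subj),
                          trial = 1:n_trial)
  d$session <- rep(rep(1:2, each = n_trial / 2), n_subj)
  d$condition <- rep(c("CBM-I", "EMA-only"), each = n_trial * n_subj / 2)
  x_s <- ifelse(d$session == 2, 0.5, -0.5)
  x_c <- ifelse(d$condition == "CBM-I", 0.5, -0.5)
  eta <- 1 + 0.5 * x_s + 0.6 * x_s * x_c
  d$correct <- as.integer(runif(nrow(d)) < plogis(eta))

  m <- fit_glmm(d, correct ~ session * condition + (1 | subject_id))
  fx <- tidy(m)
  expect_true(all(c("odds.ratio", "conf.low", "conf.high") %in% names(fx)))
  inter <- fx[fx$term == "session2:conditionCBM-I", ]
  expect_lt(abs(inter$estimate - 0.6), 2 * inter$std.error)
  ses <- fx[fx$term == "session2", ]
  expect_lt(abs(ses$estimate - 0.5), 2 * ses$std.error)

  # intercept-only model on balanced data reproduces the observed odds
  m0 <- fit_glmm(d, correct ~ 1 + (1 | subject_id))
  obs_odds <- mean(d$correct) / (1 - mean(d$correct))
  expect_equal(exp(tidy(m0)$estimate[1]), obs_odds, tolerance = 0.1)
  expect_equal(m0$ranef$sigma2, pi^2 / 3)

  expect_error(fit_glmm(d, trial ~ session + (1 | subject_id)), "binary")
})

test_that("marginal-mean contrasts respect the Tukey family and adjustment", {
  design <- make_design(40, 40, seed = 3)
  rates <- simulate_rates(design, seed = 4)
  m <- fit_lmm(rates, learning_rate ~ session * condition + (1 | subject_id))

  # two-level factor: a family of one, adjustment leaves p unchanged
  ct_t <- emm_contrasts(m, "session", adjust = "tukey")
  ct_n <- emm_contrasts(m, "session", adjust = "none")
  expect_equal(nrow(ct_t), 1L)
  expect_equal(ct_t$p.value, ct_n$p.value, tolerance = 1e-10)

  # sliced by condition: one contrast per slice
  ct_by <- emm_contrasts(m, "session", by = "condition")
  expect_equal(nrow(ct_by), 2L)

  expect_error(emm_contrasts(m, "banana"), "banana")
})

test_that("Tukey-adjusted p-values match the studentized-range computation", {
  set.seed(21)
  n_subj <- 30
  d <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:n_subj),
                          grp = c("a", "b", "c"))
  d$y <- 0.3 + 0.05 * (d$grp == "b") + rnorm(nrow(d), 0, 0.08) +
    rep(rnorm(n_subj, 0, 0.04), each = 3)
  m <- fit_lmm(d, y ~ grp + (1 | subject_id))
  ct <- emm_contrasts(m, "grp", adjust = "tukey")
  expect_equal(nrow(ct), 3L)
  # independent oracle: p = P(q_{3, df} > |t| * sqrt(2))
  oracle <- stats::ptukey(abs(ct$statistic) * sqrt(2), nmeans = 3,
                          df = ct$df, lower.tail = FALSE)
  expect_equal(ct$p.value, oracle, tolerance = 1e-6)
  # adjusted p never below unadjusted p
  raw <- emm_contrasts(m, "grp", adjust = "none")
  expect_true(all(ct$p.value >= raw$p.value - 1e-12))
})

test_that("effect sizes standardize by the total random SD", {
  design <- make_design(40, 40, seed = 5)
  rates <- simulate_rates(design, seed = 6)
  m <- fit_lmm(rates, learning_rate ~ session * condition + (1 | subject_id))
  ct <- emm_contrasts(m, "session", by = "condition")
  d <- effect_size(ct, m)
  expect_equal(d$cohens_d,
               d$estimate / sqrt(m$ranef$tau00 + m$ranef$sigma2))
  expect_equal(sign(d$cohens_d), sign(d$estimate))

  fake <- structure(list(ranef = list(tau00 = 0, sigma2 = 0)),
                    class = c("srl_lmm", "srl_model"))
  expect_error(effect_size(ct, fake), "zero")
})

test_that("the run report assembles every stage and flags missing ones", {
  study <- simulate_study(tiny_config(), seed = 41)
  design <- make_design(30, 30, seed = 7)
  rates <- simulate_rates(design, seed = 8)
  m <- fit_lmm(rates,
               learning_rate ~ session * condition * pe_valence +
                 (1 | subject_id))

  full <- report(list(study = study, rate_model = m,
                      accuracy_model = NULL, seed = 41))
  expect_true(any(grepl("Learning rates", full)))
  expect_true(any(grepl("Stage missing", full)))
  expect_true(any(grepl("Master seed: 41", full)))

  # identical inputs give identical text
  expect_identical(full, report(list(study = study, rate_model = m,
                                     accuracy_model = NULL, seed = 41)))

  path <- withr::local_tempfile(fileext = ".md")
  report(list(rate_model = m), path = path)
  expect_true(file.exists(path))
})
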