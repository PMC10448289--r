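test_that("study design has the requested arm sizes and reproducible ids", {
  d <- make_design(51, 55, seed = 1)
  expect_equal(nrow(d), 106L)
  expect_equal(sum(d$condition == "CBM-I"), 51L)
  expect_equal(sum(d$condition == "EMA-only"), 55L)
  expect_equal(anyDuplicated(d$subject_id), 0L)
  expect_identical(d, make_design(51, 55, seed = 1))
  expect_equal(nrow(make_design(0, 0, seed = 1)), 0L)
})

test_that("outcome sampling follows the chosen face's contingency", {
  expect_true(all(sample_outcome(c("p80", "p20"), "p80", 50,
                                 p_reward = 1) == "happy"))
  expect_true(all(sample_outcome(c("p80", "p20"), "p80", 50,
                                 p_reward = 0) == "angry"))
  expect_error(sample_outcome(c("p80", "p20"), "p70"),
               class = "srl_validation_error")
  set.seed(4)
  draws <- sample_outcome(c("p70", "p30"), "p70", 20000)
  expect_equal(mean(draws == "happy"), 0.7, tolerance = 0.02)
})

test_that("training simulation honors degenerate parameter settings", {
  sch <- make_schedule(10, 2, 0)

  # zero learning rates: expected values never move from initialization
  frozen <- simulate_training(q_params(0, 0, 5), sch, seed = 2)
  expect_true(all(frozen$q == 0.5))

  # indifferent agent: choice fraction near one half (pooled over runs)
  sch_big <- make_schedule(50, 4, 0)
  frac_a <- mean(vapply(1:10, function(s) {
    tr <- simulate_training(q_params(0.3, 0.3, 0), sch_big, seed = s)$trials
    mean(tr$chosen == tr$face_a)
  }, numeric(1)))
  expect_lt(abs(frac_a - 0.5), 0.015)

  # determinism
  a <- simulate_training(q_params(0.3, 0.2, 5), sch, seed = 9)
  b <- simulate_training(q_params(0.3, 0.2, 5), sch, seed = 9)
  expect_identical(a, b)

  # a learning agent beats chance on the strongest pair late in training
  learn <- simulate_training(q_params(0.3, 0.3, 5), make_schedule(20, 4, 0),
                             seed = 5)
  tr <- learn$trials
  strong <- tr[(tr$face_a == "p80" | tr$face_b == "p80"), ]
  late <- utils::tail(strong, 40)
  expect_gt(mean(late$chosen == "p80"), 0.5)
})

test_that("testing simulation freezes values and matches the logistic rule", {
  sch <- make_schedule(1, 1, 50)
  q <- setNames(c(0.99, 0.6, 0.55, 0.45, 0.4, 0.01), srl_faces())

  te <- simulate_testing(q, beta = 50, sch, seed = 3)
  expect_true(all(te$outcome == "none"))
  strong <- te[(te$face_a == "p80" & te$face_b == "p20") |
                 (te$face_a == "p20" & te$face_b == "p80"), ]
  expect_true(all(strong$chosen == "p80"))

  expect_error(simulate_testing(q[-1], 5, sch, seed = 1),
               class = "srl_validation_error")

  # beta = 1, value difference 0.5: closed-form choice probability 0.6225
  q2 <- setNames(c(1.0, 0.5, 0.5, 0.5, 0.5, 0.5), srl_faces())
  sch2 <- structure(list(
    training = training_pairs()[0, ],
    test = tibble::tibble(face_a = "p80", face_b = "p70",
                          p_a = 0.8, p_b = 0.7, n = 50000L)
  ), class = "srl_schedule")
  te2 <- simulate_testing(q2, beta = 1, sch2, seed = 8)
  expect_equal(mean(te2$chosen == "p80"), plogis(0.5), tolerance = 0.01)
})

test_that("false feedback adds a bounded random integer and clips", {
  expect_error(generate_feedback(101), class = "srl_validation_error")
  expect_error(generate_feedback(-1), class = "srl_validation_error")
  set.seed(6)
  fb_hi <- generate_feedback(rep(100L, 2000))
  expect_true(all(fb_hi >= 50 & fb_hi <= 100))
  expect_equal(max(fb_hi), 100L)
  fb_lo <- generate_feedback(rep(0L, 2000))
  expect_true(all(fb_lo >= 0 & fb_lo <= 50))
  expect_equal(min(fb_lo), 0L)
  fb_mid <- generate_feedback(rep(50L, 5000))
  expect_true(all(abs(fb_mid - 50L) <= 50L))
})

test_that("speech records follow the single-update rule exactly when noiseless", {
  pre <- tibble::tibble(item_id = 1:20,
                        valence = rep(c("good", "poor"), each = 10),
                        pre_rating = rep(c(40L, 60L), 10))

  # no updating: post equals pre
  none <- simulate_speech(pre, weights = 0, noise_sd = 0, seed = 3)
  expect_equal(none$post_rating, as.numeric(none$pre_rating))

  # full updating: post equals feedback
  full <- simulate_speech(pre, weights = 1, noise_sd = 0, seed = 3)
  zero_pe <- full$feedback_rating == full$pre_rating
  expect_equal(full$post_rating[!zero_pe],
               as.numeric(full$feedback_rating[!zero_pe]))
  expect_equal(full$post_rating[zero_pe], as.numeric(full$pre_rating[zero_pe]))

  # half-way updating: post sits midway between pre and feedback
  half <- simulate_speech(pre, weights = 0.5, noise_sd = 0, seed = 3)
  expect_equal(half$post_rating,
               half$pre_rating + 0.5 * (half$feedback_rating - half$pre_rating) *
                 (half$feedback_rating != half$pre_rating))
})

test_that("a full synthetic study is internally consistent and reproducible", {
  cfg <- tiny_config()
  study <- simulate_study(cfg, seed = 11)

  expect_equal(nrow(study$design), 4L)
  counts <- dplyr::count(study$trials, .data$subject_id, .data$session,
                         .data$phase)
  expect_true(all(counts$n[counts$phase == "train"] == 30L))
  expect_true(all(counts$n[counts$phase == "test"] == 30L))
  expect_equal(nrow(counts), 4 * 2 * 2)

  # speech only exists at session 2 by design: one record set per subject
  expect_equal(nrow(study$speech), 4 * 20)
  expect_no_error(validate_speech(study$speech))

  # ground truth covers every subject-session
  expect_equal(nrow(study$truth$q_params), 8L)
  expect_true(all(study$truth$q_params$alpha_reward >= 0 &
                    study$truth$q_params$alpha_reward <= 1))

  # reproducibility: identical master seed, identical artifacts
  study2 <- simulate_study(cfg, seed = 11)
  expect_identical(study$trials, study2$trials)
  expect_identical(study$speech, study2$speech)
  expect_false(identical(study$trials,
                         simulate_study(cfg, seed = 12)$trials))

  # written artifacts are re-readable
  dir <- withr::local_tempdir()
  write_study(study, dir)
  expect_identical(as.data.frame(read_trials(file.path(dir, "trials.csv"))),
                   as.data.frame(study$trials))
})

test_that("generated learning rates carry the configured effects", {
  design <- make_design(400, 400, seed = 2)
  rates <- simulate_rates(
    design,
    rates = list(mean_alpha = 0.3, sd_subject = 0.02, sd_cell = 0.02,
                 effects = list(session = 0.1, condition = 0, valence = 0,
                                session_condition = 0, session_valence = 0,
                                condition_valence = 0,
                                session_condition_valence = 0),
                 clip = c(0.001, 0.999)),
    seed = 5
  )
  by_session <- tapply(rates$learning_rate, rates$session, mean)
  expect_equal(unname(by_session["2"] - by_session["1"]), 0.1,
               tolerance = 0.01)
  expect_equal(mean(rates$learning_rate), 0.3, tolerance = 0.01)
})
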