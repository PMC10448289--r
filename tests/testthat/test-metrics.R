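make_test_trial <- function(face_a, face_b, chosen) {
  tibble::tibble(
    subject_id = "S1", condition = "CBM-I", session = 1L, phase = "test",
    trial_index = seq_along(face_a) - 1L, face_a = face_a, face_b = face_b,
    chosen = chosen, outcome = "none"
  )
}

test_that("test pairs partition into choose-reward, avoid-punish and excluded", {
  pairs <- test_pairs()
  trials <- make_test_trial(pairs$face_a, pairs$face_b, pairs$face_a)
  trials$trial_index <- seq_len(nrow(trials)) - 1L
  lab <- label_test_trials(trials)
  expect_equal(sum(lab$label == "choose_reward"), 4L)
  expect_equal(sum(lab$label == "avoid_punish"), 4L)
  expect_equal(sum(lab$label == "excluded"), 7L)
  expect_true(all(lab$label %in% c("choose_reward", "avoid_punish", "excluded")))

  one <- label_test_trials(make_test_trial("p80", "p60", "p80"))
  expect_equal(one$label, "choose_reward")
  expect_true(one$correct)
  two <- label_test_trials(make_test_trial("p20", "p30", "p30"))
  expect_equal(two$label, "avoid_punish")
  expect_true(two$correct)
  three <- label_test_trials(make_test_trial("p80", "p20", "p20"))
  expect_equal(three$label, "excluded")
  expect_false(three$correct)

  train <- make_test_trial("p80", "p60", "p80")
  train$phase <- "train"
  train$outcome <- "happy"
  expect_error(label_test_trials(train), class = "srl_validation_error")
})

test_that("accuracy proportions match a hand count on a small fixture", {
  fx <- make_test_trial(
    face_a = c("p80", "p80", "p80", "p80", "p20", "p20", "p20", "p80"),
    face_b = c("p70", "p60", "p40", "p30", "p70", "p30", "p40", "p20"),
    chosen = c("p80", "p80", "p80", "p30", "p70", "p30", "p20", "p80")
  )
  acc <- accuracy_table(fx)
  # choose_reward: chose p80 in 3 of 4 eligible pairs
  cr <- acc[acc$label == "choose_reward", ]
  expect_equal(cr$n_trials, 4L)
  expect_equal(cr$accuracy, 3 / 4)
  # avoid_punish: correct on p70 and p30, wrong on p40-vs-p20
  ap <- acc[acc$label == "avoid_punish", ]
  expect_equal(ap$n_trials, 3L)
  expect_equal(ap$accuracy, 2 / 3)

  # a random chooser converges to one half
  pairs <- test_pairs()[rep(1:15, 40), ]
  set.seed(3)
  pick <- ifelse(runif(600) < 0.5, pairs$face_a, pairs$face_b)
  rand <- make_test_trial(pairs$face_a, pairs$face_b, pick)
  racc <- accuracy_table(rand)
  expect_lt(abs(sum(racc$n_correct) / sum(racc$n_trials) - 0.5), 0.05)
})

test_that("prediction-error valence reverses for poor-performance items", {
  expect_equal(classify_pe("good", 40, 70), "positive")
  expect_equal(classify_pe("good", 70, 40), "negative")
  expect_equal(classify_pe("poor", 60, 30), "positive")
  expect_equal(classify_pe("poor", 30, 60), "negative")
  expect_equal(classify_pe("good", 50, 50), "zero")
  expect_equal(classify_pe("poor", 50, 50), "zero")

  # antisymmetry: flipping item valence and reflecting feedback about the
  # pre-rating leaves the classification unchanged
  set.seed(4)
  pre <- sample(20:80, 200, replace = TRUE)
  fb <- sample(0:100, 200, replace = TRUE)
  v <- sample(c("good", "poor"), 200, replace = TRUE)
  flipped <- ifelse(v == "good", "poor", "good")
  expect_equal(classify_pe(v, pre, fb),
               classify_pe(flipped, pre, 2 * pre - fb))
})

test_that("item weights are the fractional movement toward feedback", {
  expect_equal(item_weight(40, 80, 60), 0.5)
  expect_equal(item_weight(40, 80, 40), 0)
  expect_equal(item_weight(40, 80, 80), 1)
  expect_equal(item_weight(40, 80, 100), 1.5)  # overshoot representable
  expect_equal(item_weight(40, 80, 20), -0.5)  # counter-updating too
  expect_true(is.na(item_weight(40, 40, 60)))
})

test_that("aggregation schemes are consistent and exact on noiseless data", {
  # constant-weight subject: every scheme returns the same value
  pre <- rep(c(30L, 60L), 10)
  sp <- simulate_speech(
    tibble::tibble(item_id = 1:20, valence = rep(c("good", "poor"), each = 10),
                   pre_rating = pre),
    weights = 0.5, noise_sd = 0, seed = 6
  ) |>
    dplyr::mutate(subject_id = "S1", condition = "CBM-I", .before = 1)
  for (scheme in c("one", "pe_valence", "item_valence", "four")) {
    w <- aggregate_weights(sp, scheme)
    expect_true(all(abs(w$weight[w$n_items > 0] - 0.5) < 1e-12),
                info = scheme)
  }

  # item-valence-specific truth is recovered exactly per category
  cells <- c(positive_good = 0.3, negative_good = 0.3,
             positive_poor = 0.6, negative_poor = 0.6)
  sp2 <- simulate_speech(
    tibble::tibble(item_id = 1:20, valence = rep(c("good", "poor"), each = 10),
                   pre_rating = pre),
    weights = cells, noise_sd = 0, seed = 7
  ) |>
    dplyr::mutate(subject_id = "S1", condition = "CBM-I", .before = 1)
  wv <- aggregate_weights(sp2, "item_valence")
  expect_equal(wv$weight[wv$category == "good"], 0.3, tolerance = 1e-12)
  expect_equal(wv$weight[wv$category == "poor"], 0.6, tolerance = 1e-12)

  # the one-weight scheme equals the item-count-weighted mean of the
  # pe-valence categories
  wp <- aggregate_weights(sp2, "pe_valence")
  wo <- aggregate_weights(sp2, "one")
  expect_equal(wo$weight,
               sum(wp$weight * wp$n_items) / sum(wp$n_items),
               tolerance = 1e-12)

  # zero-PE items are excluded with a recorded reason (deterministic fixture)
  pre3 <- rep(40L, 20)
  fb3 <- c(40L, rep(80L, 9), rep(20L, 10))  # item 1 has zero PE
  sp3 <- speech_fixture(pre = pre3, feedback = fb3,
                        post = pre3 + 0.5 * (fb3 - pre3))
  w3 <- aggregate_weights(sp3, "one")
  excl <- attr(w3, "excluded")
  expect_equal(nrow(excl), 1L)
  expect_equal(excl$item_id, 1L)
  expect_match(excl$reason, "zero prediction error")
  expect_equal(w3$n_items, 19L)

  # the regression estimator agrees with the mean on constant weights
  wr <- aggregate_weights(sp, "one", estimator = "regression")
  expect_equal(wr$weight, 0.5, tolerance = 1e-12)
})

test_that("influence screening removes planted outliers and is idempotent", {
  # balanced fixture with equal-magnitude residuals orthogonal to every
  # model term: no observation is influential by construction
  n <- 40
  sgn <- rep(c(1, 1, -1, -1), length.out = n)
  base <- tibble::tibble(
    subject_id = rep(sprintf("S%02d", 1:n), each = 2),
    condition = rep(rep(c("CBM-I", "EMA-only"), each = 2), n / 2),
    category = rep(c("negative", "positive"), n),
    weight = 0.5 + 0.02 * rep(sgn, each = 2) * rep(c(1, -1), n)
  )

  clean <- screen_outliers(base)
  expect_equal(clean$n_removed, 0L)

  planted <- base
  planted$weight[7] <- 5
  scr <- screen_outliers(planted)
  expect_gte(scr$n_removed, 1L)
  expect_true(5 %in% scr$removed$weight)
  expect_false(5 %in% scr$retained$weight)

  # threshold Inf removes nothing
  none <- screen_outliers(planted, threshold = Inf)
  expect_equal(none$n_removed, 0L)

  # screening its own retained output removes nothing further
  again <- screen_outliers(scr$retained)
  expect_equal(again$n_removed, 0L)
  expect_equal(nrow(again$retained), nrow(scr$retained))
})
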