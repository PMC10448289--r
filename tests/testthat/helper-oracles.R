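# Independent straight-line oracles and fixture builders, deliberately
# written without reference to the package's internals.

# Step-by-step replay of the asymmetric Q-learning likelihood: plain R,
# scalar arithmetic, no shared code with the package's compiled version.
oracle_replay <- function(trials, alpha_reward, alpha_punish, beta, q0 = 0.5) {
  faces <- c("p80", "p70", "p60", "p40", "p30", "p20")
  q <- setNames(rep(q0, 6), faces)
  pw <- numeric(nrow(trials))
  for (t in seq_len(nrow(trials))) {
    a <- trials$face_a[t]
    b <- trials$face_b[t]
    p_a <- 1 / (1 + exp(-beta * (q[[a]] - q[[b]])))
    pw[t] <- log(if (trials$chosen[t] == a) p_a else 1 - p_a)
    ch <- trials$chosen[t]
    out <- as.integer(trials$outcome[t] == "happy")
    pe <- out - q[[ch]]
    alpha <- if (pe > 0) {
      alpha_reward
    } else if (pe < 0) {
      alpha_punish
    } else if (out == 1) alpha_reward else alpha_punish
    q[[ch]] <- q[[ch]] + alpha * pe
  }
  list(nll = -sum(pw), pointwise = pw, q = q)
}

# Random but valid training-trial fixture (any faces may be paired; the
# likelihood does not require the training contingency structure).
random_train_fixture <- function(n, seed) {
  set.seed(seed)
  faces <- c("p80", "p70", "p60", "p40", "p30", "p20")
  pair <- t(replicate(n, sample(faces, 2)))
  chosen <- ifelse(runif(n) < 0.5, pair[, 1], pair[, 2])
  tibble::tibble(
    subject_id = "T1",
    condition = "CBM-I",
    session = 1L,
    phase = "train",
    trial_index = seq_len(n) - 1L,
    face_a = pair[, 1],
    face_b = pair[, 2],
    chosen = chosen,
    outcome = sample(c("happy", "angry"), n, replace = TRUE)
  )
}

# Minimal valid speech fixture with fully controlled ratings.
speech_fixture <- function(subject_id = "T1", condition = "CBM-I",
                           pre, feedback, post) {
  tibble::tibble(
    subject_id = subject_id,
    condition = condition,
    item_id = 1:20,
    valence = rep(c("good", "poor"), each = 10),
    pre_rating = as.integer(pre),
    feedback_rating = as.integer(feedback),
    post_rating = post
  )
}

tiny_config <- function(...) {
  study_config(task = list(n_cbmi = 2, n_ema = 2, reps_per_pair = 5,
                           blocks = 2, test_reps = 2), ...)
}
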