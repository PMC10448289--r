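# Synthetic-cohort generator: study design, task environment, Q-learning
# agents, and speech-task records with known ground truth.

#' Generate a study design
#'
#' Creates `n_cbmi + n_ema` subjects with unique ids, randomly assigned (by
#' shuffling) to the CBM-I intervention arm or the EMA-only comparison arm.
#' All subjects are present at both laboratory sessions.
#'
#' @param n_cbmi,n_ema Number of subjects per condition (defaults are the
#'   arm sizes of the emulated study: 51 and 55).
#' @param seed Seed for the condition assignment.
#' @return A tibble with `subject_id`, `condition` and `sessions_present`.
#' @examples
#' make_design(2, 2, seed = 1)
#' @export
make_design <- function(n_cbmi = 51, n_ema = 55, seed = 1) {
  stopifnot(n_cbmi >= 0, n_ema >= 0)
  n <- n_cbmi + n_ema
  cond <- with_seed(seed, sample(rep(conditions(), c(n_cbmi, n_ema))))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    condition = as.character(cond),
    sessions_present = rep("1,2", n)
  )
}

#' Sample a task outcome for a chosen face
#'
#' Draws the happy/angry outcome delivered when `chosen` is selected from a
#' training pair: happy with the chosen face's reward probability, angry
#' otherwise. The probability defaults to the contingency encoded in the
#' face id (e.g. 0.8 for `"p80"`).
#'
#' @param pair Character vector of the two face ids shown.
#' @param chosen The face selected; must be a member of `pair`.
#' @param n Number of independent outcome draws.
#' @param p_reward Optional override of the reward probability.
#' @return Character vector of `"happy"` / `"angry"` outcomes.
#' @examples
#' set.seed(1)
#' table(sample_outcome(c("p80", "p20"), "p80", n = 1000))
#' @export
sample_outcome <- function(pair, chosen, n = 1, p_reward = NULL) {
  stopifnot(length(pair) == 2, length(chosen) == 1)
  if (!chosen %in% pair) {
    abort("chosen face is not a member of the pair",
          class = "srl_validation_error")
  }
  p <- p_reward %||% face_prob(chosen)
  stopifnot(p >= 0, p <= 1)
  ifelse(runif(n) < p, "happy", "angry")
}

# Expand a pair table (face_a, face_b, p_a, p_b, n) into a shuffled trial
# order with randomized left/right placement (placement is not modeled).
expand_pairs <- function(pairs) {
  rows <- rep(seq_len(nrow(pairs)), pairs$n)
  rows <- sample(rows)
  out <- pairs[rows, c("face_a", "face_b", "p_a", "p_b")]
  flip <- runif(nrow(out)) < 0.5
  out[flip, c("face_a", "face_b", "p_a", "p_b")] <-
    out[flip, c("face_b", "face_a", "p_b", "p_a")]
  out
}

#' Simulate the training phase for one Q-learning agent
#'
#' Plays the scheduled training presentations with a softmax policy over
#' the agent's current expected values, sampling each outcome from the
#' chosen face's reward contingency and updating the chosen face's value
#' with the valence-appropriate learning rate (happy = 1, angry = 0; values
#' start at 0.5).
#'
#' @param params An [q_params()] object: the agent's true parameters.
#' @param schedule An [make_schedule()] object.
#' @param seed Seed for choices, outcomes and trial order.
#' @param q0 Initial expected value (scalar, applied to all six faces).
#' @return A list with `trials` (a phase-`"train"` trial tibble without
#'   subject columns) and `q` (the named vector of terminal expected
#'   values, for handoff to [simulate_testing()]).
#' @export
simulate_training <- function(params, schedule, seed = 1, q0 = 0.5) {
  stopifnot(inherits(schedule, "srl_schedule"))
  with_seed(seed, {
    seq_tab <- expand_pairs(schedule$training)
    n <- nrow(seq_tab)
    q <- setNames(rep(q0, length(srl_faces())), srl_faces())
    chosen <- character(n)
    outcome <- character(n)
    for (t in seq_len(n)) {
      a <- seq_tab$face_a[t]
      b <- seq_tab$face_b[t]
      p_a <- choice_prob(q[[a]], q[[b]], params$beta)
      ch <- if (runif(1) < p_a) a else b
      p_rew <- if (ch == a) seq_tab$p_a[t] else seq_tab$p_b[t]
      out <- if (runif(1) < p_rew) "happy" else "angry"
      q[[ch]] <- q_update(q[[ch]], as.integer(out == "happy"), params)
      chosen[t] <- ch
      outcome[t] <- out
    }
    list(
      trials = tibble::tibble(
        phase = "train",
        trial_index = seq_len(n) - 1L,
        face_a = seq_tab$face_a,
        face_b = seq_tab$face_b,
        chosen = chosen,
        outcome = outcome
      ),
      q = q
    )
  })
}

#' Simulate the no-feedback testing phase
#'
#' Plays the recombined test pairs with a softmax policy over frozen
#' expected values: no outcomes are delivered and no learning occurs
#' (`outcome = "none"` on every trial).
#'
#' @param q Named vector of expected values for all six faces (typically
#'   the terminal values from [simulate_training()]).
#' @param beta Inverse temperature of the frozen policy.
#' @param schedule An [make_schedule()] object.
#' @param seed Seed for choices and trial order.
#' @return A phase-`"test"` trial tibble without subject columns.
#' @export
simulate_testing <- function(q, beta, schedule, seed = 1) {
  stopifnot(inherits(schedule, "srl_schedule"))
  missing <- setdiff(srl_faces(), names(q))
  if (length(missing) > 0) {
    abort(paste0("Missing expected values for face(s): ",
                 paste(missing, collapse = ", ")),
          class = "srl_validation_error")
  }
  with_seed(seed, {
    seq_tab <- expand_pairs(schedule$test)
    p_a <- choice_prob(q[seq_tab$face_a], q[seq_tab$face_b], beta)
    pick_a <- runif(nrow(seq_tab)) < p_a
    tibble::tibble(
      phase = "test",
      trial_index = seq_len(nrow(seq_tab)) - 1L,
      face_a = seq_tab$face_a,
      face_b = seq_tab$face_b,
      chosen = ifelse(pick_a, seq_tab$face_a, seq_tab$face_b),
      outcome = "none"
    )
  })
}

#' Generate false judge feedback for a speech item
#'
#' Implements the false-feedback rule of the speech-expectancies task: a
#' random integer drawn uniformly from -50..50 is added to the participant's
#' pre-speech self-rating and the result is clipped to the 0-100 rating
#' scale.
#'
#' @param pre_rating Integer self-rating(s) in \[0, 100\].
#' @return Integer feedback rating(s) in \[0, 100\], one per input.
#' @examples
#' set.seed(1)
#' generate_feedback(c(50, 100, 0))
#' @export
generate_feedback <- function(pre_rating) {
  if (any(pre_rating < 0 | pre_rating > 100 | pre_rating != floor(pre_rating))) {
    abort("pre_rating must be integers within [0, 100]",
          class = "srl_validation_error")
  }
  u <- sample(-50:50, length(pre_rating), replace = TRUE)
  as.integer(pmin(pmax(pre_rating + u, 0), 100))
}

#' Four-cell true update weights from an additive configuration
#'
#' Builds the four (PE valence x item valence) true update weights from a
#' base weight plus a PE-valence effect and an item-valence effect, each
#' applied as +/- effect/2 with positive PEs and poor items on the + side.
#'
#' @param w A list with elements `base`, `pe`, `item`.
#' @return Named numeric vector with cells `positive_good`,
#'   `positive_poor`, `negative_good`, `negative_poor`.
#' @examples
#' speech_weight_cells(list(base = 0.52, pe = 0.20, item = 0.11))
#' @export
speech_weight_cells <- function(w) {
  c(
    positive_good = w$base + w$pe / 2 - w$item / 2,
    positive_poor = w$base + w$pe / 2 + w$item / 2,
    negative_good = w$base - w$pe / 2 - w$item / 2,
    negative_poor = w$base - w$pe / 2 + w$item / 2
  )
}

#' Simulate one subject's speech-expectancies records
#'
#' Draws false feedback for each item with [generate_feedback()], then sets
#' the post-speech expectancy to
#' `pre + w * (feedback - pre) + noise`, where `w` is the subject's true
#' update weight for the item's (PE valence, item valence) cell, the noise
#' is Gaussian with SD `noise_sd`, and the result is clipped to \[0, 100\]
#' after the noise is added. Items with zero prediction error
#' (feedback equal to the pre-rating) receive no update.
#'
#' @param pre Tibble with `item_id`, `valence` (10 `"good"` and 10 `"poor"`
#'   items) and integer `pre_rating` in \[0, 100\].
#' @param weights Named numeric vector of true update weights for the four
#'   cells `positive_good`, `positive_poor`, `negative_good`,
#'   `negative_poor` (see [speech_weight_cells()] for the additive builder),
#'   or a single number applied to all cells.
#' @param noise_sd Post-rating noise SD in rating points.
#' @param seed Seed for feedback and noise.
#' @return A speech-item tibble (without subject columns) with feedback and
#'   post ratings.
#' @export
simulate_speech <- function(pre, weights, noise_sd = 8, seed = 1) {
  stopifnot(all(c("item_id", "valence", "pre_rating") %in% names(pre)))
  if (length(weights) == 1 && is.null(names(weights))) {
    weights <- setNames(rep(weights, 4),
                        c("positive_good", "positive_poor",
                          "negative_good", "negative_poor"))
  }
  with_seed(seed, {
    fb <- generate_feedback(pre$pre_rating)
    pe <- classify_pe(pre$valence, pre$pre_rating, fb)
    cell <- paste0(pe, "_", pre$valence)
    w <- ifelse(pe == "zero", 0, unname(weights[cell]))
    post <- pre$pre_rating + w * (fb - pre$pre_rating) +
      rnorm(nrow(pre), sd = noise_sd)
    tibble::tibble(
      item_id = pre$item_id,
      valence = pre$valence,
      pre_rating = as.integer(pre$pre_rating),
      feedback_rating = fb,
      post_rating = pmin(pmax(post, 0), 100)
    )
  })
}

#' Generate true learning rates for a cohort
#'
#' Draws each subject's true learning rate per session and prediction-error
#' valence from the additive model the inference stage targets: grand mean
#' plus configured session, condition and valence effects (entered through
#' +/- 1/2 effects coding, session 2 / CBM-I / positive on the + side) plus
#' a subject-level random intercept and cell-level noise, clipped to the
#' configured open interval inside \[0, 1\].
#'
#' @param design A [make_design()] tibble.
#' @param rates The `task$rates` section of an [study_config()].
#' @param seed Seed for all draws.
#' @return A tibble with one row per subject x session x PE valence and a
#'   `learning_rate` column of true generative rates.
#' @export
simulate_rates <- function(design, rates = study_config()$task$rates, seed = 1) {
  e <- rates$effects
  grid <- tidyr::expand_grid(
    design[, c("subject_id", "condition")],
    session = c(1L, 2L),
    pe_valence = c("negative", "positive")
  )
  with_seed(seed, {
    b_subj <- setNames(rnorm(nrow(design), sd = rates$sd_subject),
                       design$subject_id)
    x_s <- ifelse(grid$session == 2L, 0.5, -0.5)
    x_c <- ifelse(grid$condition == "CBM-I", 0.5, -0.5)
    x_v <- ifelse(grid$pe_valence == "positive", 0.5, -0.5)
    mu <- rates$mean_alpha +
      e$session * x_s + e$condition * x_c + e$valence * x_v +
      e$session_condition * x_s * x_c +
      e$session_valence * x_s * x_v +
      e$condition_valence * x_c * x_v +
      e$session_condition_valence * x_s * x_c * x_v
    raw <- mu + b_subj[grid$subject_id] + rnorm(nrow(grid), sd = rates$sd_cell)
    grid$learning_rate <- pmin(pmax(raw, rates$clip[1]), rates$clip[2])
    grid
  })
}

#' Simulate a complete synthetic study
#'
#' Generates the full set of artifacts the analysis pipeline consumes:
#' a study design, both sessions of the selection task played by Q-learning
#' agents with known parameters (training plus recombined no-feedback
#' testing), session-2 speech-expectancies records generated from known
#' update weights, and the ground-truth parameter tables needed for
#' recovery studies. All randomness is driven by per-subject substreams
#' derived from the master seed, so identical seeds give identical tables.
#'
#' @param config An [study_config()] object.
#' @param seed Master seed.
#' @return An object of class `srl_study`: a list with tibbles `design`,
#'   `trials`, `speech`, and `truth` (a list with `q_params` — true
#'   alpha/beta per subject-session — and `speech_weights` — true update
#'   weights per subject cell).
#' @examples
#' study <- simulate_study(study_config(task = list(n_cbmi = 2, n_ema = 2)), seed = 1)
#' dplyr::count(study$trials, session, phase)
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "srl_config"))
  task <- config$task
  schedule <- make_schedule(task$reps_per_pair, task$blocks, task$test_reps)
  seeds <- derive_seeds(seed, 3)
  design <- make_design(task$n_cbmi, task$n_ema, seed = seeds[1])
  n <- nrow(design)
  if (n == 0) {
    empty_trials <- tibble::tibble(
      subject_id = character(), condition = character(), session = integer(),
      phase = character(), trial_index = integer(), face_a = character(),
      face_b = character(), chosen = character(), outcome = character()
    )
    return(structure(list(design = design, trials = empty_trials,
                          speech = tibble::tibble(), truth = list(),
                          config = config, seed = seed),
                     class = "srl_study"))
  }

  rates <- simulate_rates(design, task$rates, seed = seeds[2])
  q_truth <- rates |>
    tidyr::pivot_wider(names_from = "pe_valence", values_from = "learning_rate") |>
    dplyr::rename(alpha_reward = "positive", alpha_punish = "negative")
  q_truth$beta <- with_seed(seeds[3],
    exp(rnorm(nrow(q_truth), task$beta$meanlog, task$beta$sdlog)))

  sub_seeds <- derive_seeds(seed + 1L, n)
  per_subject <- purrr::map(seq_len(n), function(i) {
    sid <- design$subject_id[i]
    cond <- design$condition[i]
    s_seeds <- derive_seeds(sub_seeds[i], 5)
    sessions <- purrr::map(1:2, function(ses) {
      pars <- q_truth |>
        dplyr::filter(.data$subject_id == sid, .data$session == ses)
      params <- q_params(pars$alpha_reward, pars$alpha_punish, pars$beta)
      tr <- simulate_training(params, schedule, seed = s_seeds[2 * ses - 1])
      te <- simulate_testing(tr$q, params$beta, schedule, seed = s_seeds[2 * ses])
      dplyr::bind_rows(tr$trials, te) |>
        dplyr::mutate(subject_id = sid, condition = cond,
                      session = as.integer(ses), .before = 1)
    })
    sp <- task$speech
    w_cells <- speech_weight_cells(sp$weights[[cond]])
    pre <- with_seed(s_seeds[4], tibble::tibble(
      item_id = 1:20,
      valence = rep(c("good", "poor"), each = 10),
      pre_rating = sample(sp$pre_min:sp$pre_max, 20, replace = TRUE)
    ))
    speech <- simulate_speech(pre, w_cells, noise_sd = sp$noise_sd,
                              seed = s_seeds[5]) |>
      dplyr::mutate(subject_id = sid, condition = cond, .before = 1)
    list(trials = dplyr::bind_rows(sessions), speech = speech,
         weights = tibble::tibble(subject_id = sid, condition = cond,
                                  cell = names(w_cells),
                                  true_weight = unname(w_cells)))
  })

  trials <- purrr::map_dfr(per_subject, "trials")
  speech <- purrr::map_dfr(per_subject, "speech")
  weights <- purrr::map_dfr(per_subject, "weights")
  validate_trials(trials)
  validate_speech(speech)

  structure(
    list(design = design, trials = trials, speech = speech,
         truth = list(q_params = q_truth, speech_weights = weights,
                      rates = rates),
         config = config, seed = seed),
    class = "srl_study"
  )
}

#' @export
print.srl_study <- function(x, ...) {
  cat("<srl_study> ", nrow(x$design), " subjects (",
      sum(x$design$condition == "CBM-I"), " CBM-I / ",
      sum(x$design$condition == "EMA-only"), " EMA-only); ",
      nrow(x$trials), " trials; ", nrow(x$speech), " speech items\n", sep = "")
  invisible(x)
}

#' Write the artifacts of a synthetic study to a directory
#'
#' Emits `trials.csv`, `speech.csv`, `design.csv` and `truth.json` (the
#' ground-truth parameter tables plus the master seed).
#'
#' @param study An [simulate_study()] result.
#' @param dir Output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "srl_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trials(study$trials, file.path(dir, "trials.csv"))
  write_speech(study$speech, file.path(dir, "speech.csv"))
  readr::write_csv(study$design, file.path(dir, "design.csv"))
  jsonlite::write_json(
    list(seed = study$seed,
         q_params = study$truth$q_params,
         speech_weights = study$truth$speech_weights),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}
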