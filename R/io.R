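# Tabular I/O and validation for trial and speech-item tables.
#
# Both tables are comma-delimited UTF-8 with fixed headers so that fixtures
# are diffable and language-neutral:
#   trials: subject_id, condition, session, phase, trial_index,
#           face_a, face_b, chosen, outcome
#   speech: subject_id, condition, item_id, valence, pre_rating,
#           feedback_rating, post_rating

trial_columns <- function() {
  c("subject_id", "condition", "session", "phase", "trial_index",
    "face_a", "face_b", "chosen", "outcome")
}

speech_columns <- function() {
  c("subject_id", "condition", "item_id", "valence", "pre_rating",
    "feedback_rating", "post_rating")
}

conditions <- function() c("CBM-I", "EMA-only")

check_columns <- function(data, expected, what) {
  missing <- setdiff(expected, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing column(s) in ", what, " table: ",
                 paste(missing, collapse = ", ")),
          class = "srl_schema_error")
  }
  invisible(data)
}

row_fail <- function(bad, msg) {
  if (any(bad)) {
    rows <- which(bad)
    shown <- paste(head(rows, 5), collapse = ", ")
    if (length(rows) > 5) shown <- paste0(shown, ", ...")
    abort(paste0(msg, " (row ", shown, ")"), class = "srl_validation_error")
  }
}

#' Validate a trial or speech-item table
#'
#' Checks every structural invariant of the documented table schemas:
#' known condition labels, sessions in \{1, 2\}, faces drawn from the six
#' task faces, the chosen face being a member of its pair, outcomes present
#' during training and absent (`"none"`) in the testing phase, 0-based trial
#' indices strictly increasing within subject x session x phase, ratings in
#' \[0, 100\], and exactly 10 good and 10 poor items per speech subject.
#' Violations raise a classed error naming the offending rows; nothing is
#' silently coerced.
#'
#' @param trials,speech A data frame in the documented trial / speech layout.
#' @return The validated table, invisibly, as a tibble.
#' @export
validate_trials <- function(trials) {
  check_columns(trials, trial_columns(), "trial")
  trials <- tibble::as_tibble(trials)
  if (nrow(trials) == 0) {
    return(invisible(trials))
  }
  row_fail(!trials$condition %in% conditions(),
           "condition must be 'CBM-I' or 'EMA-only'")
  row_fail(!trials$session %in% c(1L, 2L), "session must be 1 or 2")
  row_fail(!trials$phase %in% c("train", "test"),
           "phase must be 'train' or 'test'")
  row_fail(!trials$face_a %in% srl_faces(), "unknown face_a id")
  row_fail(!trials$face_b %in% srl_faces(), "unknown face_b id")
  row_fail(trials$face_a == trials$face_b, "pair faces must be distinct")
  row_fail(!(trials$chosen == trials$face_a | trials$chosen == trials$face_b),
           "chosen face is not a member of its pair")
  row_fail(!trials$outcome %in% c("happy", "angry", "none"),
           "outcome must be 'happy', 'angry' or 'none'")
  row_fail(trials$phase == "test" & trials$outcome != "none",
           "test-phase trials must have outcome 'none'")
  row_fail(trials$phase == "train" & trials$outcome == "none",
           "train-phase trials must have a 'happy' or 'angry' outcome")
  row_fail(trials$trial_index < 0 | trials$trial_index != floor(trials$trial_index),
           "trial_index must be a non-negative integer")
  inc <- trials |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$subject_id, .data$session, .data$phase) |>
    dplyr::mutate(.bad = c(FALSE, diff(.data$trial_index) <= 0)) |>
    dplyr::ungroup()
  row_fail(seq_len(nrow(trials)) %in% inc$.row[inc$.bad],
           "trial_index must be strictly increasing within subject x session x phase")
  invisible(trials)
}

#' @rdname validate_trials
#' @export
validate_speech <- function(speech) {
  check_columns(speech, speech_columns(), "speech")
  speech <- tibble::as_tibble(speech)
  if (nrow(speech) == 0) {
    return(invisible(speech))
  }
  row_fail(!speech$condition %in% conditions(),
           "condition must be 'CBM-I' or 'EMA-only'")
  row_fail(!speech$valence %in% c("good", "poor"),
           "item valence must be 'good' or 'poor'")
  row_fail(!speech$item_id %in% 1:20, "item_id must be in 1..20")
  for (col in c("pre_rating", "feedback_rating", "post_rating")) {
    row_fail(speech[[col]] < 0 | speech[[col]] > 100,
             paste0(col, " must be within [0, 100]"))
  }
  counts <- speech |>
    dplyr::count(.data$subject_id, .data$valence)
  bad <- counts$n != 10L
  if (any(bad)) {
    abort(paste0("Each subject needs exactly 10 good and 10 poor items; ",
                 "violated for subject(s) ",
                 paste(unique(counts$subject_id[bad]), collapse = ", ")),
          class = "srl_validation_error")
  }
  invisible(speech)
}

trial_col_types <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    condition = readr::col_character(),
    session = readr::col_integer(),
    phase = readr::col_character(),
    trial_index = readr::col_integer(),
    face_a = readr::col_character(),
    face_b = readr::col_character(),
    chosen = readr::col_character(),
    outcome = readr::col_character()
  )
}

speech_col_types <- function() {
  readr::cols(
    subject_id = readr::col_character(),
    condition = readr::col_character(),
    item_id = readr::col_integer(),
    valence = readr::col_character(),
    pre_rating = readr::col_integer(),
    feedback_rating = readr::col_integer(),
    post_rating = readr::col_double()
  )
}

#' Read and write trial and speech-item tables
#'
#' CSV readers and writers for the two documented table layouts. Every read
#' validates the table against its invariants (see [validate_trials()]);
#' writes preserve row order so that a write/read round trip reproduces the
#' records exactly.
#'
#' @param path Path to a CSV file.
#' @param trials,speech A valid trial / speech table.
#' @return The readers return a validated tibble; the writers return `path`
#'   invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  trials <- suppressWarnings(readr::read_csv(path, col_types = trial_col_types()))
  check_columns(trials, trial_columns(), "trial")
  validate_trials(trials)
  trials
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials[, trial_columns()], path)
  invisible(path)
}

#' @rdname read_trials
#' @export
read_speech <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  speech <- suppressWarnings(readr::read_csv(path, col_types = speech_col_types()))
  check_columns(speech, speech_columns(), "speech")
  validate_speech(speech)
  speech
}

#' @rdname read_trials
#' @export
write_speech <- function(speech, path) {
  validate_speech(speech)
  readr::write_csv(speech[, speech_columns()], path)
  invisible(path)
}
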