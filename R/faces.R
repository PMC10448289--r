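#' Faces and pair schedules of the social probabilistic selection task
#'
#' The task presents six neutral faces whose identifiers name their reward
#' contingency: face `"p80"` becomes happy on 80% of the trials on which it
#' is chosen (and angry otherwise), `"p70"` on 70%, and so on down to
#' `"p20"`. During training the faces appear only in the three complementary
#' pairs 80/20, 70/30 and 60/40; during the no-feedback testing phase they
#' are recombined into all 15 unordered pairs.
#'
#' @return `srl_faces()` returns the six face identifiers, ordered from most
#'   rewarding to most punishing. `face_prob()` returns the reward
#'   (happy-outcome) probability encoded by each identifier.
#' @examples
#' srl_faces()
#' face_prob("p80")
#' @export
srl_faces <- function() {
  c("p80", "p70", "p60", "p40", "p30", "p20")
}

#' @param face Character vector of face identifiers (e.g. `"p80"`).
#' @rdname srl_faces
#' @export
face_prob <- function(face) {
  bad <- !face %in% srl_faces()
  if (any(bad)) {
    abort(paste0("Unknown face id(s): ", paste(unique(face[bad]), collapse = ", ")))
  }
  as.numeric(sub("^p", "", face)) / 100
}

#' Training and testing pair schedules
#'
#' `training_pairs()` returns the three complementary training pairs (80/20,
#' 70/30, 60/40). `test_pairs()` returns all 15 unordered pairs of the six
#' faces used in the recombined testing phase. `make_schedule()` bundles both
#' with trial counts into a task schedule.
#'
#' @return A tibble with columns `face_a`, `face_b` (and reward
#'   probabilities `p_a`, `p_b`); for `make_schedule()` an object of class
#'   `srl_schedule` with elements `training` and `test`, each a pair table
#'   with an `n` column of presentation counts.
#' @examples
#' training_pairs()
#' make_schedule(reps_per_pair = 20, blocks = 4, test_reps = 4)
#' @export
training_pairs <- function() {
  tibble::tibble(
    face_a = c("p80", "p70", "p60"),
    face_b = c("p20", "p30", "p40"),
    p_a = face_prob(c("p80", "p70", "p60")),
    p_b = face_prob(c("p20", "p30", "p40"))
  )
}

#' @rdname training_pairs
#' @export
test_pairs <- function() {
  faces <- srl_faces()
  idx <- utils::combn(length(faces), 2)
  tibble::tibble(
    face_a = faces[idx[1, ]],
    face_b = faces[idx[2, ]],
    p_a = face_prob(faces[idx[1, ]]),
    p_b = face_prob(faces[idx[2, ]])
  )
}

#' @param reps_per_pair Training presentations of each pair per block.
#' @param blocks Number of training blocks.
#' @param test_reps Repetitions of each recombined pair in the testing phase.
#' @rdname training_pairs
#' @export
make_schedule <- function(reps_per_pair = 20, blocks = 4, test_reps = 4) {
  stopifnot(reps_per_pair >= 0, blocks >= 0, test_reps >= 0)
  training <- training_pairs()
  training$n <- as.integer(reps_per_pair * blocks)
  test <- test_pairs()
  test$n <- as.integer(test_reps)
  structure(list(training = training, test = test), class = "srl_schedule")
}

#' @export
print.srl_schedule <- function(x, ...) {
  cat("<srl_schedule>\n")
  cat("  training:", sum(x$training$n), "trials over",
      nrow(x$training), "complementary pairs\n")
  cat("  test:    ", sum(x$test$n), "trials over",
      nrow(x$test), "recombined pairs (no feedback)\n")
  invisible(x)
}
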