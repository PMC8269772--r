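# Session logs: JSON round-trip of a full test transcript, CSV flat export,
# and re-scoring of logged sessions.

#' Write an acuity test session log to JSON
#'
#' Serialises a complete test transcript (configuration, every letter
#' presentation, anchor and final score) so the session can be re-scored or
#' audited later. Numbers are written at full precision so
#' [read_session()] round-trips the log exactly.
#'
#' @param test an `acuity_test` from [run_test()].
#' @param path output file path.
#' @param subject_id,setting,test_index session identifiers stored in the
#'   log (setting is an opaque label such as `"clinic"` or `"home"`).
#' @return `path`, invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".json")
#' write_session(run_test(deterministic_observer(0.3)), tmp, "s01", "clinic", 1)
#' @export
write_session <- function(test, path, subject_id = "unknown",
                          setting = "unknown", test_index = 1L) {
  stopifnot(inherits(test, "acuity_test"))
  payload <- list(
    subject_id = subject_id,
    setting = setting,
    test_index = as.integer(test_index),
    config = unclass(test$config),
    trials = test$trials,
    smallest_recognized_logmar = test$smallest_recognized_logmar,
    anchor_logmar = test$anchor_logmar,
    letters_correct_below_anchor = test$letters_correct_below_anchor,
    va_logmar = test$va_logmar,
    status = test$status
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Read an acuity test session log
#'
#' @param path a JSON file written by [write_session()].
#' @return A list with `subject_id`, `setting`, `test_index`, and `test`
#'   (the reconstructed `acuity_test`).
#' @export
read_session <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(staircase_config, raw$config)
  trials <- tibble::as_tibble(raw$trials)
  trials$letter_index <- as.integer(trials$letter_index)
  trials$trial <- as.integer(trials$trial)
  test <- new_acuity_test(
    va = raw$va_logmar %||% NA_real_,
    anchor = raw$anchor_logmar %||% NA_real_,
    letters_below = as.integer(raw$letters_correct_below_anchor %||% NA_integer_),
    status = raw$status,
    trials = trials,
    smallest_recognized = raw$smallest_recognized_logmar %||% NA_real_,
    config = cfg
  )
  list(
    subject_id = raw$subject_id, setting = raw$setting,
    test_index = as.integer(raw$test_index), test = test
  )
}

#' Re-score a logged session
#'
#' Recomputes the single-letter score from the trial transcript in a session
#' log, independently of the score stored in the file.
#'
#' @param path a JSON session log.
#' @return A one-row tibble: `subject_id`, `setting`, `test_index`,
#'   `va_logmar`, `anchor_logmar`, `letters_correct_below_anchor`, `status`,
#'   and `matches_logged` (whether the recomputed score equals the stored
#'   one).
#' @export
score_session <- function(path) {
  s <- read_session(path)
  sc <- letter_score(s$test$trials, s$test$config)
  logged <- s$test$va_logmar
  tibble::tibble(
    subject_id = s$subject_id, setting = s$setting, test_index = s$test_index,
    va_logmar = sc$va_logmar, anchor_logmar = sc$anchor_logmar,
    letters_correct_below_anchor = sc$letters_correct_below_anchor,
    status = sc$status,
    matches_logged = isTRUE(all.equal(sc$va_logmar, logged)) ||
      (is.na(sc$va_logmar) && is.na(logged))
  )
}

#' Export a session transcript as a flat CSV
#'
#' One row per letter presentation, with session identifiers repeated.
#'
#' @inheritParams write_session
#' @return `path`, invisibly.
#' @export
export_session_csv <- function(test, path, subject_id = "unknown",
                               setting = "unknown", test_index = 1L) {
  stopifnot(inherits(test, "acuity_test"))
  flat <- dplyr::mutate(test$trials,
    subject_id = subject_id, setting = setting,
    test_index = as.integer(test_index), .before = 1
  )
  readr::write_csv(flat, path)
  invisible(path)
}
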