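# Two-phase adaptive acuity staircase: coarse single-letter range finding,
# then five-letter-per-line thresholding with single-letter scoring.

#' Staircase configuration
#'
#' Parameters of the adaptive acuity test. Defaults follow the standard
#' computerised protocol: range finding in 0.2 logMAR steps from 0.8 logMAR,
#' thresholding with five crowded letters per line in 0.1 logMAR steps until
#' all five letters on one line are wrong, scored at 0.02 logMAR credit per
#' correct letter. The identity `score_increment * letters_per_line ==
#' thresh_step` (0.02 x 5 = 0.1) is required: full credit for a line moves
#' the score down exactly one line.
#'
#' @param start_logmar range-finding start size (default 0.8).
#' @param range_step range-finding step (default 0.2).
#' @param thresh_step thresholding line step (default 0.1).
#' @param letters_per_line letters per thresholding line (default 5).
#' @param score_increment logMAR credit per correct letter (default 0.02).
#' @param grid_floor,grid_ceiling smallest and largest presentable sizes
#'   (defaults -0.3 and 1.6).
#' @param refresh_enabled re-present a letter once per line if the first
#'   response on the line is an error (attention-lapse refresh); the
#'   refreshed response replaces the original. Off by default.
#' @param max_refresh_per_line maximum refreshes per line (default 1).
#' @return A `staircase_config` list.
#' @examples
#' staircase_config()
#' @export
staircase_config <- function(start_logmar = 0.8, range_step = 0.2,
                             thresh_step = 0.1, letters_per_line = 5L,
                             score_increment = 0.02,
                             grid_floor = -0.3, grid_ceiling = 1.6,
                             refresh_enabled = FALSE,
                             max_refresh_per_line = 1L) {
  if (range_step <= 0 || thresh_step <= 0 || score_increment <= 0) {
    abort("All step sizes must be positive.", class = "acuitysim_domain_error")
  }
  if (abs(score_increment * letters_per_line - thresh_step) > 1e-9) {
    abort("`score_increment * letters_per_line` must equal `thresh_step`.",
      class = "acuitysim_domain_error"
    )
  }
  if (!(grid_floor < start_logmar && start_logmar <= grid_ceiling)) {
    abort("Need grid_floor < start_logmar <= grid_ceiling.",
      class = "acuitysim_domain_error"
    )
  }
  cfg <- list(
    start_logmar = start_logmar, range_step = range_step,
    thresh_step = thresh_step, letters_per_line = as.integer(letters_per_line),
    score_increment = score_increment,
    grid_floor = grid_floor, grid_ceiling = grid_ceiling,
    refresh_enabled = isTRUE(refresh_enabled),
    max_refresh_per_line = as.integer(max_refresh_per_line)
  )
  # integer hundredths used throughout the engine
  for (f in c(
    "start_logmar", "range_step", "thresh_step", "score_increment",
    "grid_floor", "grid_ceiling"
  )) {
    if (abs(cfg[[f]] * 100 - round(cfg[[f]] * 100)) > 1e-9) {
      abort(sprintf("`%s` must lie on a 0.01 logMAR grid.", f),
        class = "acuitysim_domain_error"
      )
    }
  }
  structure(cfg, class = "staircase_config")
}

# mutable trial log shared by the phases
new_trial_log <- function() {
  env <- new.env(parent = emptyenv())
  env$phase <- character()
  env$size <- integer()
  env$letter <- integer()
  env$correct <- logical()
  env$refreshed <- logical()
  env
}

log_trial <- function(log, phase, size_h, letter, correct, refreshed = FALSE) {
  log$phase <- c(log$phase, phase)
  log$size <- c(log$size, size_h)
  log$letter <- c(log$letter, letter)
  log$correct <- c(log$correct, correct)
  log$refreshed <- c(log$refreshed, refreshed)
}

trials_tibble <- function(log) {
  tibble::tibble(
    trial = seq_along(log$phase),
    phase = log$phase,
    size_logmar = h_to_lm(log$size),
    letter_index = log$letter,
    correct = log$correct,
    refreshed = log$refreshed
  )
}

ask <- function(observer, size_h) {
  r <- observer$respond(h_to_lm(size_h))
  if (!is.logical(r) || length(r) != 1L || is.na(r)) {
    abort("Observer failed to answer the presentation.",
      class = "acuitysim_protocol_error"
    )
  }
  r
}

#' Range finding: coarse single-letter threshold search
#'
#' Presents a single crowded letter in 0.2 logMAR steps from the start size
#' (default 0.8): descending while responses are correct, or ascending from
#' an incorrect start until a size is recognised. The smallest recognised
#' size anchors the thresholding phase, which starts 0.2 logMAR larger
#' (clamped to the grid ceiling). An incorrect response at the ceiling ends
#' the test as off-scale-high; a correct response at the floor makes the
#' floor the smallest recognised size.
#'
#' @param observer an `acuity_observer`.
#' @param config a [staircase_config()].
#' @return A list: `smallest_recognized_logmar`, `thresholding_start_logmar`
#'   (NA when off scale), `status` (`"ok"` or `"off_scale_high"`), and
#'   `trials`, a tibble of single-letter presentations.
#' @examples
#' range_find(deterministic_observer(0.3), staircase_config())
#' @export
range_find <- function(observer, config = staircase_config()) {
  stopifnot(inherits(observer, "acuity_observer"), inherits(config, "staircase_config"))
  log <- new_trial_log()
  res <- range_find_impl(observer, config, log)
  list(
    smallest_recognized_logmar = if (is.na(res$smallest)) NA_real_ else h_to_lm(res$smallest),
    thresholding_start_logmar = if (is.na(res$start)) NA_real_ else h_to_lm(res$start),
    status = res$status,
    trials = trials_tibble(log)
  )
}

range_find_impl <- function(observer, config, log) {
  floor_h <- lm_to_h(config$grid_floor)
  ceil_h <- lm_to_h(config$grid_ceiling)
  step_h <- lm_to_h(config$range_step)
  size <- lm_to_h(config$start_logmar)

  r <- ask(observer, size)
  log_trial(log, "range_finding", size, 0L, r)
  if (r) {
    smallest <- size
    while (size > floor_h) {
      size <- max(size - step_h, floor_h)
      r <- ask(observer, size)
      log_trial(log, "range_finding", size, 0L, r)
      if (!r) break
      smallest <- size
    }
  } else {
    smallest <- NA_integer_
    while (size < ceil_h) {
      size <- min(size + step_h, ceil_h)
      r <- ask(observer, size)
      log_trial(log, "range_finding", size, 0L, r)
      if (r) {
        smallest <- size
        break
      }
    }
    if (is.na(smallest)) {
      return(list(smallest = NA_integer_, start = NA_integer_, status = "off_scale_high"))
    }
  }
  list(
    smallest = smallest,
    start = min(smallest + step_h, ceil_h),
    status = "ok"
  )
}

# Present one five-letter line at size_h; returns logical vector of length
# letters_per_line. When a window is configured the line is chunked for
# display feasibility (chunking never changes scoring). With refresh enabled,
# each incorrect response may be re-presented up to max_refresh_per_line
# times per line; the refreshed response replaces the original.
present_line <- function(observer, size_h, config, log, window = NULL) {
  n <- config$letters_per_line
  if (!is.null(window)) {
    chunk_line(
      h_to_lm(size_h), window$distance_mm,
      window$window_width_mm, window$window_height_mm
    )
  }
  responses <- logical(n)
  refreshes_left <- if (config$refresh_enabled) config$max_refresh_per_line else 0L
  for (i in seq_len(n)) {
    r <- ask(observer, size_h)
    refreshed <- FALSE
    if (!r && refreshes_left > 0L) {
      r <- ask(observer, size_h)
      refreshed <- TRUE
      refreshes_left <- refreshes_left - 1L
    }
    log_trial(log, "thresholding", size_h, i - 1L, r, refreshed)
    responses[i] <- r
  }
  responses
}

#' Thresholding: five-letter lines to termination
#'
#' Presents five crowded letters per line, descending in 0.1 logMAR steps
#' until all five letters on one line are wrong, or until the floor line is
#' completed (full stop with credit). If the first presented line has one or
#' more errors, sequentially larger lines are presented until all five
#' responses on a line are correct, and thresholding descends from that size;
#' sizes already attempted during the ascent are not re-presented - their
#' recorded responses are reused. If the ascent reaches the ceiling without a
#' clean line the result is off-scale-high.
#'
#' @inheritParams range_find
#' @param start_logmar first line size (on the grid), typically from
#'   [range_find()].
#' @param window optional display constraint: a list with `distance_mm`,
#'   `window_width_mm`, `window_height_mm`; lines are chunked to fit
#'   (chunking never affects scoring).
#' @return A list: `trials` tibble of letter presentations, `status`
#'   (`"ok"` or `"off_scale_high"`).
#' @examples
#' run_thresholding(deterministic_observer(0.3), 0.6, staircase_config())
#' @export
run_thresholding <- function(observer, start_logmar,
                             config = staircase_config(), window = NULL) {
  stopifnot(inherits(observer, "acuity_observer"), inherits(config, "staircase_config"))
  log <- new_trial_log()
  status <- thresholding_impl(observer, lm_to_h(start_logmar), config, log, window)
  list(trials = trials_tibble(log), status = status)
}

thresholding_impl <- function(observer, start_h, config, log, window = NULL) {
  floor_h <- lm_to_h(config$grid_floor)
  ceil_h <- lm_to_h(config$grid_ceiling)
  step_h <- lm_to_h(config$thresh_step)
  attempted <- new.env(parent = emptyenv()) # size -> response vector

  present <- function(size_h) {
    r <- present_line(observer, size_h, config, log, window)
    assign(as.character(size_h), r, envir = attempted)
    r
  }

  first <- present(start_h)
  top_clean <- start_h
  if (!all(first)) {
    # ascend until a fully-correct line
    s <- start_h
    top_clean <- NA_integer_
    while (s < ceil_h) {
      s <- min(s + step_h, ceil_h)
      if (all(present(s))) {
        top_clean <- s
        break
      }
    }
    if (is.na(top_clean)) {
      return("off_scale_high")
    }
  }
  # descend from the clean line, reusing recorded responses
  s <- top_clean
  while (s > floor_h) {
    s <- s - step_h
    key <- as.character(s)
    r <- if (exists(key, envir = attempted)) get(key, envir = attempted) else present(s)
    if (!any(r)) {
      return("ok") # all five wrong: failure criterion met
    }
  }
  "ok" # floor line completed without termination
}

#' Single-letter scoring of a thresholding transcript
#'
#' Scores a trial log to a final acuity. The anchor is the largest
#' thresholding size with all five letters correct; each correct letter at
#' sizes strictly below the anchor earns 0.02 logMAR of credit (each size
#' counted once):
#' `va = anchor - 0.02 * letters_correct_below_anchor`.
#' With 5 letters per 0.1 line this makes a perfect all-or-none observer
#' score exactly its threshold. A transcript with no fully-correct line has
#' no numeric score (off-scale-high).
#'
#' @param trials a tibble of letter trials with columns `phase`,
#'   `size_logmar`, `correct` (as produced by [run_thresholding()] or
#'   [run_test()]); only thresholding rows are scored.
#' @param config a [staircase_config()].
#' @return A list: `va_logmar`, `anchor_logmar`,
#'   `letters_correct_below_anchor`, `status`.
#' @examples
#' th <- run_thresholding(deterministic_observer(0.3), 0.6, staircase_config())
#' letter_score(th$trials, staircase_config())
#' @export
letter_score <- function(trials, config = staircase_config()) {
  stopifnot(inherits(config, "staircase_config"))
  th <- trials[trials$phase == "thresholding", , drop = FALSE]
  none <- list(
    va_logmar = NA_real_, anchor_logmar = NA_real_,
    letters_correct_below_anchor = NA_integer_, status = "off_scale_high"
  )
  if (nrow(th) == 0L) {
    return(none)
  }
  size_h <- lm_to_h(th$size_logmar)
  by_size <- split(th$correct, size_h)
  sizes <- as.integer(names(by_size))
  complete <- vapply(by_size, length, 1L) == config$letters_per_line
  clean <- vapply(by_size, all, TRUE) & complete
  if (!any(clean)) {
    return(none)
  }
  anchor <- max(sizes[clean])
  below <- sizes < anchor
  letters_below <- sum(vapply(by_size[below], sum, 1L))
  inc_h <- lm_to_h(config$score_increment)
  va_h <- anchor - inc_h * letters_below
  list(
    va_logmar = h_to_lm(va_h),
    anchor_logmar = h_to_lm(anchor),
    letters_correct_below_anchor = as.integer(letters_below),
    status = "ok"
  )
}

#' Run a complete acuity test
#'
#' Composes range finding, thresholding and single-letter scoring into one
#' acuity measurement, retaining the full trial-by-trial transcript.
#'
#' @inheritParams run_thresholding
#' @return An `acuity_test` object: a list with `va_logmar`,
#'   `anchor_logmar`, `letters_correct_below_anchor`, `status` (`"ok"`,
#'   `"off_scale_high"`; `"off_scale_low"` is reserved), `trials` (tibble of
#'   every letter presentation across both phases),
#'   `smallest_recognized_logmar`, and `config`. Use [tidy()] for the trial
#'   log and [glance()] for a one-row summary.
#' @examples
#' run_test(deterministic_observer(0.3))
#' @export
run_test <- function(observer, config = staircase_config(), window = NULL) {
  stopifnot(inherits(observer, "acuity_observer"), inherits(config, "staircase_config"))
  log <- new_trial_log()
  rf <- range_find_impl(observer, config, log)
  if (rf$status != "ok") {
    return(new_acuity_test(
      NA_real_, NA_real_, NA_integer_, "off_scale_high",
      trials_tibble(log), NA_real_, config
    ))
  }
  th_status <- thresholding_impl(observer, rf$start, config, log, window)
  trials <- trials_tibble(log)
  if (th_status != "ok") {
    return(new_acuity_test(
      NA_real_, NA_real_, NA_integer_, th_status,
      trials, h_to_lm(rf$smallest), config
    ))
  }
  sc <- letter_score(trials, config)
  new_acuity_test(
    sc$va_logmar, sc$anchor_logmar, sc$letters_correct_below_anchor,
    sc$status, trials, h_to_lm(rf$smallest), config
  )
}

new_acuity_test <- function(va, anchor, letters_below, status, trials,
                            smallest_recognized, config) {
  structure(
    list(
      va_logmar = va, anchor_logmar = anchor,
      letters_correct_below_anchor = letters_below, status = status,
      trials = trials, smallest_recognized_logmar = smallest_recognized,
      config = config
    ),
    class = "acuity_test"
  )
}

#' @export
print.acuity_test <- function(x, ...) {
  cat("<acuity_test>\n")
  if (x$status == "ok") {
    cat(sprintf(
      "  VA %.2f logMAR (anchor %.2f, %d letters credited below)\n",
      x$va_logmar, x$anchor_logmar, x$letters_correct_below_anchor
    ))
  } else {
    cat("  status:", x$status, "\n")
  }
  cat(sprintf("  %d letter presentations\n", nrow(x$trials)))
  invisible(x)
}

#' @rdname run_test
#' @param x an `acuity_test` object.
#' @param ... unused.
#' @method tidy acuity_test
#' @export
tidy.acuity_test <- function(x, ...) {
  x$trials
}

#' @rdname run_test
#' @method glance acuity_test
#' @export
glance.acuity_test <- function(x, ...) {
  tibble::tibble(
    va_logmar = x$va_logmar,
    anchor_logmar = x$anchor_logmar,
    letters_correct_below_anchor = x$letters_correct_below_anchor,
    status = x$status,
    n_trials = nrow(x$trials),
    smallest_recognized_logmar = x$smallest_recognized_logmar
  )
}
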