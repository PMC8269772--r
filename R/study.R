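# End-to-end simulator of the 2x2 study design: each synthetic subject's
# worse eye is tested twice in clinic and twice at home, and the resulting
# paired acuities are summarised Bland-Altman style.

#' Study configuration
#'
#' Parameters of the simulated clinic/home by test/retest study. Defaults
#' mirror the validation design this package models: 36 subjects, true
#' thresholds spanning -0.14 to 1.06 logMAR, 58% tested clinic-first, one
#' (worse) eye per subject. The home condition's default threshold jitter of
#' 0.04 logMAR is an illustrative value representing uncontrolled home
#' viewing conditions (screen brightness, room lighting); the clinic
#' condition is unperturbed by default.
#'
#' @param n_subjects number of subjects (default 36).
#' @param acuity_low,acuity_high true-threshold range in logMAR (defaults
#'   -0.14 and 1.06); thresholds are drawn uniformly.
#' @param slope,guess_rate,lapse_rate psychometric observer defaults
#'   (30 per logMAR, 0.1, 0.01).
#' @param clinic_effect,home_effect [condition_effect()] per setting.
#' @param order_fraction fraction of subjects tested clinic-first
#'   (default 22/36); order is recorded but not modelled.
#' @param master_seed integer; all per-session seeds derive from it.
#' @param staircase a [staircase_config()].
#' @return A `study_config` list.
#' @examples
#' study_config(n_subjects = 10, master_seed = 42)
#' @export
study_config <- function(n_subjects = 36L, acuity_low = -0.14,
                         acuity_high = 1.06, slope = 30,
                         guess_rate = 0.1, lapse_rate = 0.01,
                         clinic_effect = condition_effect(),
                         home_effect = condition_effect(threshold_jitter_sd = 0.04),
                         order_fraction = 22 / 36, master_seed = 1L,
                         staircase = staircase_config()) {
  if (n_subjects < 2L) {
    abort("Need at least 2 subjects.", class = "acuitysim_domain_error")
  }
  if (acuity_low >= acuity_high) {
    abort("Need acuity_low < acuity_high.", class = "acuitysim_domain_error")
  }
  if (order_fraction < 0 || order_fraction > 1) {
    abort("`order_fraction` must be in [0, 1].", class = "acuitysim_domain_error")
  }
  stopifnot(
    inherits(clinic_effect, "condition_effect"),
    inherits(home_effect, "condition_effect"),
    inherits(staircase, "staircase_config")
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      acuity_low = acuity_low, acuity_high = acuity_high,
      slope = slope, guess_rate = guess_rate, lapse_rate = lapse_rate,
      clinic_effect = clinic_effect, home_effect = home_effect,
      order_fraction = order_fraction,
      master_seed = as.integer(master_seed),
      staircase = staircase
    ),
    class = "study_config"
  )
}

# Deterministic per-session seed: polynomial string hash of the master seed
# and session identifiers, reduced mod 2^31 - 1 so transcripts are
# independently reproducible from the config alone.
derive_seed <- function(master_seed, ...) {
  key <- paste(master_seed, ..., sep = "/")
  h <- (as.double(master_seed) %% 2147483647 + 2147483647) %% 2147483647
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

#' Simulate the full 2x2 study
#'
#' Draws each subject's true threshold uniformly over the configured range,
#' then runs four complete staircase tests per subject (clinic x 2,
#' home x 2), each with a psychometric observer wrapped in the setting's
#' condition effect. Per-session seeds derive deterministically from the
#' master seed, the subject id, the setting, and the test index, so the same
#' configuration always reproduces the same dataset bit for bit. Off-scale
#' sessions are kept as flagged rows, never dropped.
#'
#' @param config a [study_config()].
#' @return A `study_dataset`: a list with `config`, `subjects` (tibble of
#'   `subject_id`, `true_threshold`, `order`), `results` (tibble of
#'   `subject_id`, `setting`, `test_index`, `va_logmar`, `status`,
#'   `n_trials`, `seed`), and `sessions` (named list of `acuity_test`
#'   objects, keyed `subject/setting/test`). [tidy()] returns the results
#'   tibble joined to subject truth.
#' @examples
#' sim <- simulate_study(study_config(n_subjects = 3, master_seed = 7))
#' tidy(sim)
#' @export
simulate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  n <- config$n_subjects
  env <- new.env(parent = emptyenv())
  env$seed <- config$master_seed
  env$rng_state <- NULL
  thresholds <- with_stream(
    env, runif(n, config$acuity_low, config$acuity_high)
  )
  ids <- sprintf("s%03d", seq_len(n))
  n_clinic_first <- round(config$order_fraction * n)
  order <- ifelse(seq_len(n) <= n_clinic_first, "clinic_first", "home_first")

  effects <- list(clinic = config$clinic_effect, home = config$home_effect)
  grid <- tidyr::expand_grid(
    subject = seq_len(n), setting = c("clinic", "home"), test_index = 1:2
  )
  sessions <- vector("list", nrow(grid))
  rows <- purrr::pmap(grid, function(subject, setting, test_index) {
    id <- ids[[subject]]
    seed_obs <- derive_seed(config$master_seed, id, setting, test_index, "observer")
    seed_jit <- derive_seed(config$master_seed, id, setting, test_index, "jitter")
    obs <- psychometric_observer(
      thresholds[[subject]], config$slope,
      config$guess_rate, config$lapse_rate,
      seed = seed_obs
    )
    obs <- apply_condition(obs, effects[[setting]], session_seed = seed_jit)
    test <- run_test(obs, config$staircase)
    list(
      row = tibble::tibble(
        subject_id = id, setting = setting, test_index = test_index,
        va_logmar = test$va_logmar, status = test$status,
        n_trials = nrow(test$trials), seed = seed_obs
      ),
      test = test
    )
  })
  sessions <- purrr::map(rows, "test")
  names(sessions) <- paste(ids[grid$subject], grid$setting, grid$test_index,
    sep = "/"
  )
  structure(
    list(
      config = config,
      subjects = tibble::tibble(
        subject_id = ids, true_threshold = thresholds, order = order
      ),
      results = dplyr::bind_rows(purrr::map(rows, "row")),
      sessions = sessions
    ),
    class = "study_dataset"
  )
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf(
    "<study_dataset> %d subjects x 4 sessions (master seed %d)\n",
    x$config$n_subjects, x$config$master_seed
  ))
  flagged <- sum(x$results$status != "ok")
  if (flagged > 0) cat(" ", flagged, "flagged (off-scale) sessions\n")
  invisible(x)
}

#' @rdname simulate_study
#' @param x a `study_dataset`.
#' @param ... unused.
#' @method tidy study_dataset
#' @export
tidy.study_dataset <- function(x, ...) {
  dplyr::left_join(x$results, x$subjects, by = "subject_id")
}

#' Wide per-subject acuity table
#'
#' Reshapes a simulated study to one row per subject with columns `clinic1`,
#' `clinic2`, `home1`, `home2` (NA where a session was off-scale) plus a
#' `flags` column naming any off-scale sessions.
#'
#' @param dataset a `study_dataset`.
#' @return A tibble, one row per subject.
#' @export
study_pairs <- function(dataset) {
  stopifnot(inherits(dataset, "study_dataset"))
  flags <- dataset$results |>
    dplyr::filter(.data$status != "ok") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      flags = paste0(.data$setting, .data$test_index, ":", .data$status,
        collapse = ";"
      )
    )
  dataset$results |>
    dplyr::mutate(session = paste0(.data$setting, .data$test_index)) |>
    dplyr::select("subject_id", "session", "va_logmar") |>
    tidyr::pivot_wider(names_from = "session", values_from = "va_logmar") |>
    dplyr::left_join(dataset$subjects, by = "subject_id") |>
    dplyr::left_join(flags, by = "subject_id") |>
    dplyr::mutate(flags = dplyr::coalesce(.data$flags, "")) |>
    dplyr::select(
      "subject_id", "true_threshold", "order",
      "clinic1", "clinic2", "home1", "home2", "flags"
    )
}

#' Summarise a simulated study Bland-Altman style
#'
#' Produces the three standard comparisons: clinic vs home method comparison
#' (first clinic test vs first home test), clinic test-retest variability,
#' and home test-retest variability. Differences are first-listed minus
#' second-listed. Subjects with an off-scale session in a comparison are
#' excluded from that comparison only (their flags are retained in
#' [study_pairs()]); a comparison with fewer than 2 usable pairs is reported
#' as skipped.
#'
#' @param dataset a `study_dataset`.
#' @param loa_multiplier limits-of-agreement multiplier (default 2).
#' @return A tibble with one row per comparison (`clinic1_vs_home1`,
#'   `clinic_trv`, `home_trv`): `a`, `b`, `skipped`, and the [glance()]
#'   columns of each [bland_altman()] summary.
#' @examples
#' sim <- simulate_study(study_config(n_subjects = 8, master_seed = 7))
#' summarize_study(sim)
#' @export
summarize_study <- function(dataset, loa_multiplier = 2) {
  wide <- study_pairs(dataset)
  comparisons <- tibble::tribble(
    ~comparison, ~a, ~b,
    "clinic1_vs_home1", "clinic1", "home1",
    "clinic_trv", "clinic1", "clinic2",
    "home_trv", "home1", "home2"
  )
  purrr::pmap(comparisons, function(comparison, a, b) {
    pairs <- wide[stats::complete.cases(wide[, c(a, b)]), ]
    if (nrow(pairs) < 2L) {
      return(tibble::tibble(
        comparison = comparison, a = a, b = b, skipped = TRUE,
        n = nrow(pairs)
      ))
    }
    dplyr::bind_cols(
      tibble::tibble(comparison = comparison, a = a, b = b, skipped = FALSE),
      glance(bland_altman(pairs,
        a = !!rlang::sym(a), b = !!rlang::sym(b),
        loa_multiplier = loa_multiplier
      ))
    )
  }) |>
    dplyr::bind_rows()
}
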