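# The two-phase adaptive staircase and single-letter scoring.

test_that("range finding descends from 0.8 to the smallest recognised size", {
  rf <- range_find(deterministic_observer(0.3))
  expect_equal(rf$trials$size_logmar, c(0.8, 0.6, 0.4, 0.2))
  expect_equal(rf$trials$correct, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(rf$smallest_recognized_logmar, 0.4)
  expect_equal(rf$thresholding_start_logmar, 0.6)
  expect_identical(rf$status, "ok")
})

test_that("range finding ascends when the start size is missed", {
  rf <- range_find(deterministic_observer(0.9))
  expect_equal(rf$trials$size_logmar, c(0.8, 1.0))
  expect_equal(rf$smallest_recognized_logmar, 1.0)
  expect_equal(rf$thresholding_start_logmar, 1.2)
})

test_that("range finding clamps at floor and flags an unreachable ceiling", {
  rf <- range_find(scripted_observer(rep(TRUE, 50)))
  expect_equal(rf$smallest_recognized_logmar, -0.3)
  expect_equal(rf$thresholding_start_logmar, -0.1)
  rf_hi <- range_find(scripted_observer(rep(FALSE, 50)))
  expect_identical(rf_hi$status, "off_scale_high")
  expect_equal(max(rf_hi$trials$size_logmar), 1.6)
})

test_that("thresholding descends line by line until five letters fail", {
  th <- run_thresholding(deterministic_observer(0.3), 0.6)
  lines <- split(th$trials$correct, th$trials$size_logmar)
  expect_equal(sort(as.numeric(names(lines))), c(0.2, 0.3, 0.4, 0.5, 0.6))
  expect_true(all(vapply(lines[c("0.3", "0.4", "0.5", "0.6")], all, TRUE)))
  expect_false(any(lines[["0.2"]]))
  expect_identical(th$status, "ok")
})

test_that("a scripted partial-credit transcript scores 0.34", {
  # range finding to smallest 0.2 (start 0.4), then 5T at 0.4,
  # 3T 2F at 0.3, 5F at 0.2
  script <- c(
    TRUE, TRUE, TRUE, TRUE, FALSE, # 0.8 0.6 0.4 0.2 ok, 0.0 missed
    rep(TRUE, 5), # 0.4 line
    TRUE, TRUE, FALSE, FALSE, TRUE, # 0.3 line: 3 correct
    rep(FALSE, 5) # 0.2 line: terminate
  )
  res <- run_test(scripted_observer(script))
  expect_equal(res$anchor_logmar, 0.4)
  expect_equal(res$letters_correct_below_anchor, 3L)
  expect_equal(res$va_logmar, 0.34)
  expect_scoring_identity(res)
})

test_that("errors on the first line trigger an ascent and responses are reused", {
  # start_logmar 0.7 makes thresholding start at 0.5 for a smallest
  # recognised size of 0.3
  cfg <- staircase_config(start_logmar = 0.7)
  script <- c(
    TRUE, TRUE, TRUE, FALSE, # range: 0.7 0.5 0.3 ok, 0.1 missed
    TRUE, TRUE, FALSE, FALSE, TRUE, # 0.5 line: 2 errors -> ascend
    rep(TRUE, 5), # 0.6 line clean -> descend
    rep(FALSE, 5) # 0.4 line: terminate (0.5 reused, not re-presented)
  )
  res <- run_test(scripted_observer(script), cfg)
  th <- res$trials[res$trials$phase == "thresholding", ]
  # 0.5 presented once only: its recorded responses were reused on descent
  expect_equal(sum(abs(th$size_logmar - 0.5) < 1e-9), 5L)
  expect_equal(res$anchor_logmar, 0.6)
  expect_equal(res$letters_correct_below_anchor, 3L)
  expect_equal(res$va_logmar, 0.54)
  expect_scoring_identity(res)
})

test_that("an ascent that reaches the ceiling without a clean line is off scale", {
  # recognise 1.4 in range finding, then never produce five correct
  script <- c(
    rep(FALSE, 3), TRUE, # range: 0.8 1.0 1.2 missed, 1.4 ok -> start 1.6
    rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 1) # 1.6 line: one error, nowhere to ascend
  )
  res <- run_test(scripted_observer(c(script, rep(FALSE, 50))))
  expect_identical(res$status, "off_scale_high")
  expect_true(is.na(res$va_logmar))
})

test_that("letter scoring anchors on the largest clean line", {
  # perfect observer at 0.3: anchor 0.6 with 15 letters below
  res <- run_test(deterministic_observer(0.3))
  expect_equal(res$anchor_logmar, 0.6)
  expect_equal(res$letters_correct_below_anchor, 15L)
  expect_equal(res$va_logmar, 0.30)
  # full credit runs to the floor exactly (0.02 x 5 = 0.1 identity)
  res_floor <- run_test(deterministic_observer(-0.5))
  expect_equal(res_floor$va_logmar, -0.3)
  expect_identical(res_floor$status, "ok")
})

test_that("letter scoring without a clean line reports off scale, not a number", {
  trials <- tibble::tibble(
    phase = rep("thresholding", 5),
    size_logmar = rep(0.5, 5),
    correct = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  sc <- letter_score(trials, staircase_config())
  expect_identical(sc$status, "off_scale_high")
  expect_true(is.na(sc$va_logmar))
})

test_that("the refresh option replaces a lapsed response", {
  # deterministic threshold 0.3 with a single scripted lapse at 0.6
  lapse_once <- local({
    lapsed <- FALSE
    inner <- deterministic_observer(0.3)
    structure(
      list(
        respond = function(size) {
          if (!lapsed && abs(size - 0.6) < 1e-9) {
            lapsed <<- TRUE
            return(FALSE)
          }
          inner$respond(size)
        },
        type = "lapse_fixture", params = list()
      ),
      class = "acuity_observer"
    )
  })
  cfg <- staircase_config(refresh_enabled = TRUE)
  res <- run_test(lapse_once, cfg)
  clean <- run_test(deterministic_observer(0.3))
  expect_equal(res$va_logmar, clean$va_logmar)
  expect_true(any(res$trials$refreshed))
})

test_that("measured VA matches the grid oracle across deterministic thresholds", {
  for (t in seq(-0.2, 1.3, by = 0.05)) {
    res <- run_test(deterministic_observer(t))
    expect_equal(res$va_logmar, oracle_deterministic_va(t),
      info = sprintf("threshold %.2f", t)
    )
    expect_scoring_identity(res)
  }
})

test_that("measured VA is monotone in the deterministic threshold", {
  ts <- seq(-0.25, 1.3, by = 0.07)
  vas <- vapply(ts, function(t) run_test(deterministic_observer(t))$va_logmar, 1)
  expect_true(all(diff(vas) >= 0))
})

test_that("every observer terminates within the line-count bound", {
  cfg <- staircase_config()
  max_lines <- (cfg$grid_ceiling - cfg$grid_floor) / cfg$thresh_step +
    (cfg$grid_ceiling - cfg$grid_floor) / cfg$range_step + 2
  for (seed in 1:25) {
    res <- run_test(scripted_observer(random_script(seed)))
    n_lines <- length(unique(paste(
      res$trials$phase, res$trials$size_logmar
    )))
    expect_lte(n_lines, max_lines)
    expect_scoring_identity(res)
    # every thresholding size carries exactly five scored letters
    th <- res$trials[res$trials$phase == "thresholding", ]
    if (nrow(th) > 0) {
      expect_true(all(table(th$size_logmar) == 5))
    }
  }
})

test_that("chunked presentation never changes the score", {
  window <- list(
    distance_mm = 3000,
    window_width_mm = 120, window_height_mm = 120
  )
  plain <- run_test(deterministic_observer(0.3))
  chunked <- run_test(deterministic_observer(0.3), window = window)
  expect_identical(plain$va_logmar, chunked$va_logmar)
  expect_identical(plain$trials, chunked$trials)
})

test_that("staircase configuration enforces the scoring identity", {
  expect_error(staircase_config(score_increment = 0.03),
    class = "acuitysim_domain_error"
  )
  expect_error(staircase_config(thresh_step = -0.1),
    class = "acuitysim_domain_error"
  )
  expect_error(staircase_config(start_logmar = -0.4),
    class = "acuitysim_domain_error"
  )
  expect_error(staircase_config(start_logmar = 0.805),
    class = "acuitysim_domain_error"
  )
})

test_that("tidy and glance expose the transcript and the summary", {
  res <- run_test(deterministic_observer(0.3))
  expect_identical(tidy(res), res$trials)
  g <- glance(res)
  expect_equal(g$va_logmar, 0.30)
  expect_equal(g$n_trials, nrow(res$trials))
})
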