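# Shared fixtures and independent oracles.

# Expected acuity for an all-or-none observer: the smallest 0.1-grid size at
# or above its threshold (clamped to the floor). Independent of the engine.
oracle_deterministic_va <- function(threshold, floor = -0.3, step = 0.1) {
  grid_up <- ceiling(round((threshold - floor) / step, 9)) * step + floor
  max(round(grid_up, 9), floor)
}

# Direct Bland-Altman formula evaluation, written against the definitions
# (mean difference, n-1 SD, t-based CI, mean +/- k*SD limits of agreement).
oracle_bland_altman <- function(a, b, k = 2, conf = 0.95) {
  d <- a - b
  n <- length(d)
  bias <- sum(d) / n
  s <- sqrt(sum((d - bias)^2) / (n - 1))
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  list(
    n = n, bias = bias, sd = s, ci_low = bias - half, ci_high = bias + half,
    loa_low = bias - k * s, loa_high = bias + k * s
  )
}

# A long seeded random response script (for adversarial staircase runs).
random_script <- function(seed, n = 400, p = 0.5) {
  withr::with_seed(seed, stats::runif(n) < p)
}

# Scoring identity check on a finished test.
expect_scoring_identity <- function(test) {
  if (test$status == "ok") {
    expect_equal(
      test$va_logmar,
      test$anchor_logmar - 0.02 * test$letters_correct_below_anchor,
      tolerance = 1e-12
    )
    expect_lt(
      abs(test$va_logmar / 0.02 - round(test$va_logmar / 0.02)), 1e-9
    )
  }
  invisible(test)
}
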