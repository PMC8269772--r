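# Synthetic observers: the package's data generator. An observer is a list
# with a `respond(size_logmar)` function returning TRUE (correct) or FALSE,
# called once per presented letter.

new_observer <- function(respond, type, params = list()) {
  structure(list(respond = respond, type = type, params = params),
    class = "acuity_observer"
  )
}

#' @export
print.acuity_observer <- function(x, ...) {
  cat("<acuity_observer:", x$type, ">\n")
  if (length(x$params)) {
    utils::str(x$params, give.attr = FALSE, no.list = TRUE)
  }
  invisible(x)
}

#' Deterministic all-or-none observer
#'
#' Answers correctly if and only if the presented size is at least the
#' threshold. Stateless; the boundary is inclusive. Primarily a test oracle:
#' the staircase must measure such an observer at the smallest grid size at
#' or above its threshold.
#'
#' @param threshold_logmar true acuity threshold (logMAR).
#' @return An `acuity_observer`.
#' @examples
#' obs <- deterministic_observer(0.3)
#' obs$respond(0.3) # TRUE
#' obs$respond(0.2) # FALSE
#' @export
deterministic_observer <- function(threshold_logmar) {
  new_observer(
    function(size_logmar) size_logmar >= threshold_logmar - 1e-9,
    "deterministic",
    list(threshold_logmar = threshold_logmar)
  )
}

#' Psychometric forced-choice observer
#'
#' A standard forced-choice letter-identification observer. Per letter at
#' size `s` (logMAR),
#' `P(correct) = guess + (1 - guess - lapse) * logistic(slope * (s - threshold))`,
#' so performance is halfway between the guessing floor and the lapse ceiling
#' at the threshold. Responses are drawn from the observer's own seeded RNG
#' stream: the same parameters and seed yield an identical trial-by-trial
#' transcript, and the observer never disturbs the caller's global RNG state.
#'
#' @param threshold_logmar true threshold (logMAR).
#' @param slope psychometric steepness per logMAR; positive.
#' @param guess_rate probability correct at unreadably small sizes
#'   (default 0.1, a small-letter-set forced choice).
#' @param lapse_rate probability of error at arbitrarily large sizes
#'   (default 0.01).
#' @param seed integer seed for the observer's private RNG stream.
#' @return An `acuity_observer`.
#' @examples
#' obs <- psychometric_observer(0.3, slope = 30, seed = 1)
#' obs$respond(0.8)
#' @export
psychometric_observer <- function(threshold_logmar, slope,
                                  guess_rate = 0.1, lapse_rate = 0.01,
                                  seed = 1L) {
  if (!is.numeric(slope) || slope <= 0) {
    abort("`slope` must be positive.", class = "acuitysim_domain_error")
  }
  if (guess_rate < 0 || lapse_rate < 0 || guess_rate >= 1 - lapse_rate) {
    abort("Need 0 <= guess_rate < 1 - lapse_rate <= 1.",
      class = "acuitysim_domain_error"
    )
  }
  env <- new.env(parent = emptyenv())
  env$seed <- seed
  env$rng_state <- NULL
  p_correct <- function(s) {
    guess_rate + (1 - guess_rate - lapse_rate) *
      plogis(slope * (s - threshold_logmar))
  }
  new_observer(
    function(size_logmar) {
      with_stream(env, runif(1) < p_correct(size_logmar))
    },
    "psychometric",
    list(
      threshold_logmar = threshold_logmar, slope = slope,
      guess_rate = guess_rate, lapse_rate = lapse_rate, seed = seed,
      p_correct = p_correct
    )
  )
}

#' Scripted observer
#'
#' Replays a fixed sequence of responses, one per presented letter, for exact
#' staircase fixtures. Raises an error if the script is exhausted before the
#' test terminates.
#'
#' @param responses logical vector, consumed in order.
#' @return An `acuity_observer`.
#' @examples
#' obs <- scripted_observer(c(TRUE, TRUE, FALSE))
#' @export
scripted_observer <- function(responses) {
  responses <- as.logical(responses)
  if (anyNA(responses)) {
    abort("`responses` must be TRUE/FALSE with no NA.",
      class = "acuitysim_domain_error"
    )
  }
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  new_observer(
    function(size_logmar) {
      env$i <- env$i + 1L
      if (env$i > length(responses)) {
        abort("Scripted observer exhausted before the test terminated.",
          class = "acuitysim_script_exhausted"
        )
      }
      responses[[env$i]]
    },
    "scripted",
    list(n_responses = length(responses))
  )
}

#' Condition effect (setting-specific perturbation)
#'
#' Abstract model of a testing setting such as "at home": a multiplicative
#' calibration error on displayed sizes (mis-measured calibration cross),
#' which acts as an additive `log10(size_scale_error)` logMAR offset on every
#' presented size, plus extra between-session threshold jitter drawn once per
#' session.
#'
#' @param size_scale_error multiplicative error on displayed sizes; 1 means
#'   perfect calibration. A cross over-measured by factor c displays all
#'   letters c times too large, making the test easier by `log10(c)` logMAR.
#' @param threshold_jitter_sd between-session SD added to the observer's
#'   threshold, in logMAR.
#' @return A `condition_effect` list.
#' @examples
#' condition_effect(size_scale_error = 1.122, threshold_jitter_sd = 0.04)
#' @export
condition_effect <- function(size_scale_error = 1, threshold_jitter_sd = 0) {
  if (size_scale_error <= 0 || threshold_jitter_sd < 0) {
    abort("Need size_scale_error > 0 and threshold_jitter_sd >= 0.",
      class = "acuitysim_domain_error"
    )
  }
  structure(
    list(
      size_scale_error = size_scale_error,
      threshold_jitter_sd = threshold_jitter_sd
    ),
    class = "condition_effect"
  )
}

#' Apply a setting's condition effect to an observer
#'
#' Wraps an observer for one session: every presented size is shifted by
#' `+log10(size_scale_error)` logMAR before the observer evaluates it, and a
#' single threshold jitter draw (seeded by `session_seed`) shifts the
#' effective threshold for the whole session. Because both observer models
#' depend on size only through `size - threshold`, the jitter is applied as
#' an equal-and-opposite shift of the evaluated size.
#'
#' @param observer an `acuity_observer`.
#' @param effect a [condition_effect()].
#' @param session_seed integer seed for the session's jitter draw.
#' @return A wrapped `acuity_observer`.
#' @examples
#' obs <- apply_condition(
#'   deterministic_observer(0.3),
#'   condition_effect(size_scale_error = 10), 1
#' )
#' obs$respond(-0.6) # letters a decade oversized: reads as 0.4
#' @export
apply_condition <- function(observer, effect, session_seed = 1L) {
  stopifnot(inherits(observer, "acuity_observer"), inherits(effect, "condition_effect"))
  jitter <- 0
  if (effect$threshold_jitter_sd > 0) {
    env <- new.env(parent = emptyenv())
    env$seed <- session_seed
    env$rng_state <- NULL
    jitter <- with_stream(env, rnorm(1, 0, effect$threshold_jitter_sd))
  }
  shift <- log10(effect$size_scale_error) - jitter
  new_observer(
    function(size_logmar) observer$respond(size_logmar + shift),
    paste0(observer$type, "+condition"),
    c(observer$params, list(
      size_scale_error = effect$size_scale_error,
      threshold_jitter = jitter
    ))
  )
}
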