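# Optotype geometry, screen feasibility and physical calibration.
#
# Conventions: a logMAR-0 optotype subtends 5 arcminutes at the eye (stroke
# width 1 arcminute); letters are modelled as 5 x 5 stroke-width squares.
# Crowded layout: letters spaced 2.5 stroke widths apart, surrounded by a
# crowding box one stroke width thick, separated from the letter borders by
# 2.5 stroke widths.

ARCMIN <- pi / (180 * 60)

# crowded-chunk footprint in stroke widths; letters are 5x5-stroke squares
BOX_GAP_STROKES <- 2.5
BOX_THICK_STROKES <- 1
LETTER_GAP_STROKES <- 2.5
MARGIN_STROKES <- BOX_GAP_STROKES + BOX_THICK_STROKES # each side: 3.5
FOOTPRINT_H_STROKES <- 5 + 2 * MARGIN_STROKES # 12

footprint_w_strokes <- function(n_letters) {
  5 * n_letters + LETTER_GAP_STROKES * (n_letters - 1) + 2 * MARGIN_STROKES
}

#' Physical optotype letter height
#'
#' Converts a logMAR value and viewing distance to the physical letter height
#' required on screen. A logMAR-0 letter subtends 5 arcminutes; height scales
#' as `10^logmar`. The exact tangent is used rather than the small-angle
#' approximation.
#'
#' @param logmar logMAR value(s), dimensionless; may be off-grid.
#' @param distance_mm viewing distance in millimetres; must be positive.
#' @return Letter height in millimetres, vectorised over `logmar`.
#' @examples
#' letter_height_mm(0, 3000) # ~4.36 mm at 3 m
#' letter_height_mm(1, 3000) # one decade larger
#' @export
letter_height_mm <- function(logmar, distance_mm) {
  if (!is.numeric(distance_mm) || any(distance_mm <= 0)) {
    abort("`distance_mm` must be positive.", class = "acuitysim_domain_error")
  }
  distance_mm * tan(5 * 10^logmar * ARCMIN)
}

#' Footprint of a crowded optotype chunk
#'
#' Physical width and height of a chunk of `n_letters` crowded letters
#' (letters spaced 2.5 stroke widths apart, crowding box one stroke wide at
#' 2.5 stroke widths from the letter borders). Letters are modelled as
#' 5 x 5 stroke-width squares, so the footprint is `12` strokes tall and
#' `5k + 2.5(k-1) + 7` strokes wide for `k` letters.
#'
#' @inheritParams letter_height_mm
#' @param n_letters letters in the chunk, 1 to 5.
#' @return A tibble with columns `n_letters`, `width_mm`, `height_mm`.
#' @examples
#' crowded_footprint(0, 3000, 1)
#' crowded_footprint(0, 3000, 5)
#' @export
crowded_footprint <- function(logmar, distance_mm, n_letters) {
  if (any(n_letters < 1 | n_letters > 5 | n_letters != round(n_letters))) {
    abort("`n_letters` must be an integer between 1 and 5.",
      class = "acuitysim_domain_error"
    )
  }
  stroke <- letter_height_mm(logmar, distance_mm) / 5
  tibble::tibble(
    n_letters = as.integer(n_letters),
    width_mm = footprint_w_strokes(n_letters) * stroke,
    height_mm = FOOTPRINT_H_STROKES * stroke
  )
}

#' Screen specification
#'
#' Describes a display by diagonal and aspect ratio, plus the linear fraction
#' of each screen dimension occupied by the presentation window (a maximised
#' 16:9 video-consultation window filling two thirds of the screen is the
#' default).
#'
#' @param diagonal_in screen diagonal in inches.
#' @param aspect_w,aspect_h aspect ratio terms (default 16:9).
#' @param window_fraction linear fraction of each dimension used for letter
#'   presentation, in (0, 1]; default 2/3.
#' @return A `screen_spec` list with the inputs plus the derived
#'   `window_width_mm` and `window_height_mm` (25.4 mm per inch).
#' @examples
#' screen_spec(24)
#' @export
screen_spec <- function(diagonal_in, aspect_w = 16, aspect_h = 9,
                        window_fraction = 2 / 3) {
  if (diagonal_in <= 0 || aspect_w <= 0 || aspect_h <= 0) {
    abort("Screen diagonal and aspect terms must be positive.",
      class = "acuitysim_domain_error"
    )
  }
  if (window_fraction <= 0 || window_fraction > 1) {
    abort("`window_fraction` must be in (0, 1].",
      class = "acuitysim_domain_error"
    )
  }
  diag_mm <- diagonal_in * 25.4
  hyp <- sqrt(aspect_w^2 + aspect_h^2)
  structure(
    list(
      diagonal_in = diagonal_in, aspect_w = aspect_w, aspect_h = aspect_h,
      window_fraction = window_fraction,
      window_width_mm = diag_mm * aspect_w / hyp * window_fraction,
      window_height_mm = diag_mm * aspect_h / hyp * window_fraction
    ),
    class = "screen_spec"
  )
}

#' Derive the physical display scale from a calibration cross
#'
#' Before each session the software displays a calibration cross of known
#' size in internal display units; the user measures it physically with a
#' ruler. The ratio fixes the mm-per-unit scale used to size every optotype.
#' Scales implying a pixel density outside a plausibility window of
#' 20-600 units/inch are flagged with a warning status (gross
#' mis-measurement) but still returned.
#'
#' @param nominal_units cross length in internal display units; positive.
#' @param measured_mm physically measured length in mm; positive.
#' @return A one-row tibble: `nominal_units`, `measured_mm`, `mm_per_unit`,
#'   `units_per_inch`, `status` (`"ok"` or `"implausible_scale"`).
#' @examples
#' calibrate(100, 26.5)
#' @export
calibrate <- function(nominal_units, measured_mm) {
  if (nominal_units <= 0 || measured_mm <= 0) {
    abort("Calibration inputs must be positive.",
      class = "acuitysim_domain_error"
    )
  }
  mm_per_unit <- measured_mm / nominal_units
  upi <- 25.4 / mm_per_unit
  status <- if (upi < 20 || upi > 600) "implausible_scale" else "ok"
  if (status != "ok") {
    warn(sprintf(
      "Calibration implies %.1f units/inch, outside the 20-600 plausibility window.",
      upi
    ))
  }
  tibble::tibble(
    nominal_units = nominal_units, measured_mm = measured_mm,
    mm_per_unit = mm_per_unit, units_per_inch = upi, status = status
  )
}

#' Break a five-letter line into chunks that fit the window
#'
#' Large letter lines are broken up into singles, pairs or triplets of
#' crowded letters so they fit the presentation window; five letters are
#' always presented in total. The partition is greedy: the full five-letter
#' crowded line if it fits, otherwise repeatedly the largest chunk of 3, 2
#' or 1 letters whose crowded footprint fits both window dimensions.
#'
#' @inheritParams letter_height_mm
#' @param window_width_mm,window_height_mm presentation window size in mm.
#' @return Integer vector of chunk sizes summing to 5.
#' @examples
#' chunk_line(1.0, 3000, window_width_mm = 400, window_height_mm = 200)
#' @export
chunk_line <- function(logmar, distance_mm, window_width_mm, window_height_mm) {
  if (window_width_mm <= 0 || window_height_mm <= 0) {
    abort("Window dimensions must be positive.",
      class = "acuitysim_domain_error"
    )
  }
  fits <- function(k) {
    fp <- crowded_footprint(logmar, distance_mm, k)
    fp$width_mm <= window_width_mm && fp$height_mm <= window_height_mm
  }
  if (fits(5L)) {
    return(5L)
  }
  if (!fits(1L)) {
    abort(
      sprintf("A single crowded letter at logMAR %.2f does not fit the window.", logmar),
      class = "acuitysim_undisplayable"
    )
  }
  chunks <- integer()
  remaining <- 5L
  while (remaining > 0L) {
    k <- max(Filter(function(k) k <= remaining && fits(k), c(3L, 2L, 1L)))
    chunks <- c(chunks, k)
    remaining <- remaining - k
  }
  chunks
}

#' Largest testable logMAR on a given screen
#'
#' Scans the size grid from the ceiling downwards for the largest
#' grid-aligned logMAR whose single crowded-letter footprint fits the
#' presentation window. This is a feasibility calculator with documented
#' assumptions (square 5x5-stroke letters, crowding box included in the
#' footprint, window = `window_fraction` of each screen dimension); it is not
#' calibrated to any published device table.
#'
#' @param screen a [screen_spec()].
#' @param distance_mm viewing distance in mm.
#' @param grid_step logMAR grid step (default 0.1).
#' @param grid_floor,grid_ceiling grid bounds (defaults -0.3 and 1.6).
#' @return Largest testable logMAR on the grid.
#' @examples
#' max_testable_logmar(screen_spec(24), 3000)
#' @export
max_testable_logmar <- function(screen, distance_mm, grid_step = 0.1,
                                grid_floor = -0.3, grid_ceiling = 1.6) {
  stopifnot(inherits(screen, "screen_spec"))
  grid <- seq(grid_ceiling, grid_floor, by = -grid_step)
  for (lm in grid) {
    fp <- crowded_footprint(lm, distance_mm, 1L)
    if (fp$width_mm <= screen$window_width_mm &&
      fp$height_mm <= screen$window_height_mm) {
      return(lm)
    }
  }
  abort("No grid size fits the presentation window.",
    class = "acuitysim_undisplayable"
  )
}
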