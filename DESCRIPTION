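Package: acuitysim
Title: Simulated Computerised logMAR Acuity Testing and Agreement Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating semi-automated computerised visual-acuity
    measurement with crowded optotypes: physical optotype geometry and screen
    calibration, a two-phase adaptive staircase (range finding then
    five-letter-per-line thresholding) with single-letter scoring in 0.02
    logMAR units, synthetic forced-choice observers with configurable
    psychometric functions, Bland-Altman method-comparison and test-retest
    statistics with limits of agreement, and an end-to-end simulator of a
    clinic/home by test/retest study design. All analyses run on simulated
    observers; no clinical data are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
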