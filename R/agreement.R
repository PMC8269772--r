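# Bland-Altman method comparison and test-retest variability.

#' Bland-Altman agreement summary for paired measurements
#'
#' Summarises paired measurements by the distribution of their differences
#' `d = a - b` (first-listed minus second-listed): mean difference (bias),
#' sample SD (n - 1 denominator), a t-based 95% confidence interval of the
#' mean, and 95% limits of agreement `bias +/- loa_multiplier * sd`. The
#' limits-of-agreement multiplier is exactly 2 by default (mean plus or minus
#' two SD), with 1.96 available by option. A Shapiro-Wilk normality check of
#' the differences is reported as a diagnostic, never used as a gate.
#'
#' @param data a data frame of paired measurements.
#' @param a,b column names (unquoted or strings) holding the two paired
#'   measurements, in logMAR; defaults `a` and `b`.
#' @param loa_multiplier multiplier for the limits of agreement (default 2).
#' @param conf_level confidence level for the CI of the mean (default 0.95).
#' @return A `bland_altman` object. [tidy()] returns per-pair means and
#'   differences (the Bland-Altman plot data); [glance()] returns the
#'   one-row summary (`n`, `bias`, `sd`, `ci_low`, `ci_high`, `loa_low`,
#'   `loa_high`, `normality_p`); [autoplot()] draws the Bland-Altman plot.
#' @examples
#' pairs <- tibble::tibble(a = c(0.10, 0.20, 0.32), b = c(0.12, 0.20, 0.30))
#' ba <- bland_altman(pairs)
#' glance(ba)
#' @export
bland_altman <- function(data, a = "a", b = "b", loa_multiplier = 2,
                         conf_level = 0.95) {
  a_col <- rlang::as_name(rlang::enquo(a))
  b_col <- rlang::as_name(rlang::enquo(b))
  for (col in c(a_col, b_col)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` not found in `data`.", col),
        class = "acuitysim_input_error"
      )
    }
  }
  av <- data[[a_col]]
  bv <- data[[b_col]]
  if (!all(is.finite(av)) || !all(is.finite(bv))) {
    abort("Paired measurements must be finite.", class = "acuitysim_input_error")
  }
  n <- length(av)
  if (n < 2L) {
    abort("Bland-Altman analysis needs at least 2 pairs.",
      class = "acuitysim_insufficient_data"
    )
  }
  d <- av - bv
  bias <- mean(d)
  s <- sd(d)
  half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
  norm <- if (n >= 3L) {
    normality_check(d)
  } else {
    tibble::tibble(
      statistic = NA_real_, p_value = NA_real_, status = "insufficient_n"
    )
  }
  structure(
    list(
      n = n, bias = bias, sd = s,
      ci_low = bias - half, ci_high = bias + half,
      loa_low = bias - loa_multiplier * s,
      loa_high = bias + loa_multiplier * s,
      loa_multiplier = loa_multiplier, conf_level = conf_level,
      normality_statistic = norm$statistic, normality_p = norm$p_value,
      normality_status = norm$status,
      pairs = tibble::tibble(
        mean = (av + bv) / 2, difference = d,
        a = av, b = bv
      ),
      a_name = a_col, b_name = b_col
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman>  differences =", x$a_name, "-", x$b_name, "\n")
  cat(sprintf(
    "  n = %d, bias = %.2f, SD = %.2f logMAR\n", x$n, x$bias, x$sd
  ))
  cat(sprintf(
    "  %d%% CI of mean: (%.2f, %.2f)\n", round(100 * x$conf_level),
    x$ci_low, x$ci_high
  ))
  cat(sprintf(
    "  limits of agreement (mean +/- %g SD): (%.2f, %.2f)\n",
    x$loa_multiplier, x$loa_low, x$loa_high
  ))
  if (x$normality_status == "ok") {
    cat(sprintf("  Shapiro-Wilk p = %.3f\n", x$normality_p))
  }
  invisible(x)
}

#' @rdname bland_altman
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  x$pairs
}

#' @rdname bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    n = x$n, bias = x$bias, sd = x$sd,
    ci_low = x$ci_low, ci_high = x$ci_high,
    loa_low = x$loa_low, loa_high = x$loa_high,
    normality_p = x$normality_p
  )
}

#' @rdname bland_altman
#' @param object a `bland_altman` object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.6) +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed"
    ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("Mean of %s and %s (logMAR)", object$a_name, object$b_name),
      y = sprintf("%s - %s (logMAR)", object$a_name, object$b_name),
      title = "Bland-Altman agreement",
      subtitle = sprintf(
        "bias %.2f, limits of agreement (%.2f, %.2f)",
        object$bias, object$loa_low, object$loa_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' Normality check of paired differences
#'
#' Shapiro-Wilk test of a vector of differences, reported as a diagnostic.
#' Constant input has no defined statistic and is reported with status
#' `"degenerate"` rather than an error.
#'
#' @param differences numeric vector, n >= 3.
#' @return A one-row tibble: `statistic`, `p_value`, `status`.
#' @examples
#' normality_check(rnorm(36))
#' @export
normality_check <- function(differences) {
  if (length(differences) < 3L) {
    abort("Normality check needs at least 3 values.",
      class = "acuitysim_insufficient_data"
    )
  }
  if (diff(range(differences)) < .Machine$double.eps^0.5) {
    return(tibble::tibble(
      statistic = NA_real_, p_value = NA_real_, status = "degenerate"
    ))
  }
  sw <- shapiro.test(differences)
  tibble::tibble(
    statistic = unname(sw$statistic), p_value = sw$p.value, status = "ok"
  )
}

#' Convert a logMAR difference to ETDRS letters
#'
#' One correctly read letter on a five-letter-per-0.1-line chart is worth
#' 0.02 logMAR, so a logMAR difference divided by 0.02 gives the equivalent
#' ETDRS letter count. Results within 1e-9 of an integer are snapped to it.
#'
#' @param delta_logmar logMAR difference(s).
#' @return Letter count(s), numeric.
#' @examples
#' logmar_to_letters(0.12) # 6 letters
#' @export
logmar_to_letters <- function(delta_logmar) {
  letters <- delta_logmar / 0.02
  snap <- abs(letters - round(letters)) < 1e-9
  letters[snap] <- round(letters[snap])
  letters
}

#' Per-group Bland-Altman summaries
#'
#' Applies [bland_altman()] within each level of a grouping column (e.g. age
#' band or deprivation band, treated as opaque labels). Groups with fewer
#' than `min_n` pairs are reported as skipped rather than summarised.
#'
#' @inheritParams bland_altman
#' @param group grouping column name (unquoted or string).
#' @param min_n minimum pairs per group (default 2).
#' @return A tibble with one row per group: the group label, `skipped`
#'   flag, and the [glance()] columns of its summary (NA when skipped).
#' @examples
#' pairs <- tibble::tibble(
#'   a = c(0.1, 0.2, 0.3, 0.4), b = c(0.1, 0.22, 0.28, 0.4),
#'   group = c("child", "child", "adult", "adult")
#' )
#' subgroup_summaries(pairs, group = group)
#' @export
subgroup_summaries <- function(data, group = "group", a = "a", b = "b",
                               loa_multiplier = 2, min_n = 2L) {
  g_col <- rlang::as_name(rlang::enquo(group))
  a_col <- rlang::as_name(rlang::enquo(a))
  b_col <- rlang::as_name(rlang::enquo(b))
  if (!g_col %in% names(data)) {
    abort(sprintf("Grouping column `%s` not found in `data`.", g_col),
      class = "acuitysim_input_error"
    )
  }
  empty <- glance(bland_altman(tibble::tibble(a = c(0, 0), b = c(0, 0))))[0, ]
  data |>
    dplyr::group_by(!!rlang::sym(g_col)) |>
    dplyr::group_map(function(rows, key) {
      skipped <- nrow(rows) < min_n
      summary <- if (skipped) {
        dplyr::bind_rows(empty, tibble::tibble(n = nrow(rows)))
      } else {
        glance(bland_altman(rows,
          a = !!rlang::sym(a_col), b = !!rlang::sym(b_col),
          loa_multiplier = loa_multiplier
        ))
      }
      dplyr::bind_cols(key, tibble::tibble(skipped = skipped), summary)
    }) |>
    dplyr::bind_rows()
}
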