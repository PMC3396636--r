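#' Read a cell-count time course
#'
#' Delimited text (comma or tab, auto-detected) with header
#' `time, time_unit, count, condition`; `condition` is `dox_plus` or
#' `dox_minus`. An `aliquot_id` column, if present, is carried through.
#'
#' @param path Path to the file.
#' @return A tibble with `time`, `time_unit`, `count`, `condition` columns.
#' @export
read_count_table <- function(path) {
  tab <- .read_delimited(path)
  .require_columns(tab, c("time", "time_unit", "count", "condition"), path)
  tab <- dplyr::mutate(
    tab,
    time      = as.double(.data$time),
    time_unit = as.character(.data$time_unit),
    count     = as.double(.data$count),
    condition = as.character(.data$condition)
  )
  .one_unit(tab$time_unit)
  bad <- setdiff(unique(tab$condition), c("dox_plus", "dox_minus"))
  if (length(bad)) {
    stop("condition must be 'dox_plus' or 'dox_minus'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(tab$count <= 0)) stop("counts must be positive", call. = FALSE)
  tibble::as_tibble(tab)
}

#' Estimate the culture expansion constant j
#'
#' Regresses log cell count on time by ordinary least squares: the slope is
#' the exponential expansion constant `j` (per input time unit) and the
#' intercept is `ln(c0)`. Counts in exponential growth span orders of
#' magnitude, so the fit is performed on the log scale, where the error is
#' approximately homoscedastic; R-squared is reported on that scale. The
#' doubling time of the culture is `ln(2)/j`.
#'
#' @param counts Tibble with `time`, `count` and (optionally) `time_unit`
#'   columns; at least 3 points spanning a nonzero time range, all counts
#'   positive, times strictly increasing.
#' @param unit Time unit; taken from a `time_unit` column when present.
#' @param conf_level Confidence level for the slope CI (default 0.95).
#' @return A `growth_fit` object: fields `j`, `c0`, `r_squared`, `n_points`,
#'   `unit`, `doubling_time`, `se`, `ci` (two-sided on `j`), and the
#'   underlying `lm` fit. Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' counts <- tibble::tibble(time = seq(0, 24, 6), count = 1e4 * 2^(time / 6))
#' fit <- fit_expansion(counts, unit = "h")
#' fit$j          # ln(2)/6
#' glance(fit)
fit_expansion <- function(counts, unit = NULL, conf_level = 0.95) {
  .require_columns(counts, c("time", "count"), "counts series")
  if ("time_unit" %in% names(counts)) {
    unit <- unit %||% .one_unit(counts$time_unit, "series")
  }
  unit <- .check_unit(unit %||% stop("`unit` is required when the series ",
                                     "has no time_unit column", call. = FALSE))
  if (any(counts$count <= 0)) stop("counts must be positive", call. = FALSE)
  if (nrow(counts) < 3L) stop("need at least 3 count points", call. = FALSE)
  if (any(diff(counts$time) <= 0)) {
    stop("times within a series must be strictly increasing", call. = FALSE)
  }

  fit <- lm(log(count) ~ time, data = counts)
  s <- suppressWarnings(summary(fit))
  j <- unname(coef(fit)[["time"]])
  se <- s$coefficients["time", "Std. Error"]
  ci <- unname(suppressWarnings(confint(fit, "time",
                                        level = conf_level))[1L, ])

  structure(
    list(
      j = j,
      c0 = exp(unname(coef(fit)[["(Intercept)"]])),
      r_squared = s$r.squared,
      n_points = nrow(counts),
      unit = unit,
      doubling_time = log(2) / j,
      se = se,
      ci = ci,
      conf_level = conf_level,
      data = tibble::as_tibble(counts[c("time", "count")]),
      fit = fit
    ),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential expansion fit (%d points)\n  j = %.6g per %s  (%.0f%% CI %.6g to %.6g)\n  doubling time = %.4g %s,  c0 = %.4g cells,  R-squared (log scale) = %.4f\n",
    x$n_points, x$j, x$unit, 100 * x$conf_level, x$ci[1], x$ci[2],
    x$doubling_time, x$unit, x$c0, x$r_squared))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = c("j", "log_c0"),
    estimate = c(x$j, log(x$c0)),
    std.error = c(x$se, suppressWarnings(
      summary(x$fit)$coefficients["(Intercept)", "Std. Error"])),
    conf.low = c(x$ci[1], NA_real_),
    conf.high = c(x$ci[2], NA_real_)
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    j = x$j, c0 = x$c0, doubling_time = x$doubling_time,
    r.squared = x$r_squared, nobs = x$n_points, unit = x$unit
  )
}

#' Convert an expansion or decay rate between time units
#'
#' Exact scaling between per-minute and per-hour rates (factor 60). Set
#' `digits` for the rounded reporting convention (e.g. 0.0224 per hour prints
#' as 0.0004 per minute at 4 decimals).
#'
#' @param rate Rate constant (per `from` unit).
#' @param from,to Units, each `"min"` or `"h"`.
#' @param digits Optional rounding for a reporting view; `NULL` (default)
#'   returns the exact value.
#' @return The converted rate.
#' @export
#' @examples
#' convert_rate(0.0224, "h", "min")              # 0.0003733...
#' convert_rate(0.0224, "h", "min", digits = 4)  # 0.0004
convert_rate <- function(rate, from, to, digits = NULL) {
  .check_unit(from, "from")
  .check_unit(to, "to")
  # a rate per hour is 1/60 of the same rate per minute
  minutes_per <- c(min = 1, h = 60)
  out <- rate * minutes_per[[to]] / minutes_per[[from]]
  if (!is.null(digits)) out <- round(out, digits)
  unname(out)
}

#' Compare expansion under dox-supplemented and dox-free culture
#'
#' The reverse-chase design assumes the antibiotic does not alter cell
#' growth, so that all aliquots hold equal cell numbers at simultaneous
#' sacrifice. This fits `j` separately in each condition and reports whether
#' the confidence intervals of the two slopes overlap.
#'
#' @param counts Tibble with `time`, `count`, `condition` (values `dox_plus`,
#'   `dox_minus`) and optionally `time_unit`; or pass the two series
#'   separately via `dox_minus`.
#' @param dox_minus Optional second series when `counts` holds only the
#'   dox-supplemented one.
#' @param unit Time unit if no `time_unit` column.
#' @param conf_level Confidence level (default 0.95).
#' @return A `growth_comparison` list: `fit_dox_plus`, `fit_dox_minus`
#'   ([fit_expansion()] objects) and `ci_overlap` (logical). `tidy()` gives
#'   one row per condition.
#' @export
compare_conditions <- function(counts, dox_minus = NULL, unit = NULL,
                               conf_level = 0.95) {
  if (is.null(dox_minus)) {
    .require_columns(counts, c("time", "count", "condition"), "counts table")
    plus <- dplyr::filter(counts, .data$condition == "dox_plus")
    minus <- dplyr::filter(counts, .data$condition == "dox_minus")
  } else {
    plus <- counts
    minus <- dox_minus
  }
  fp <- fit_expansion(plus, unit = unit, conf_level = conf_level)
  fm <- fit_expansion(minus, unit = unit, conf_level = conf_level)
  overlap <- fp$ci[1] <= fm$ci[2] && fm$ci[1] <= fp$ci[2]
  structure(
    list(fit_dox_plus = fp, fit_dox_minus = fm, ci_overlap = overlap),
    class = "growth_comparison"
  )
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat("Expansion by condition:\n")
  cat(sprintf("  dox_plus : j = %.6g per %s (CI %.6g to %.6g)\n",
              x$fit_dox_plus$j, x$fit_dox_plus$unit,
              x$fit_dox_plus$ci[1], x$fit_dox_plus$ci[2]))
  cat(sprintf("  dox_minus: j = %.6g per %s (CI %.6g to %.6g)\n",
              x$fit_dox_minus$j, x$fit_dox_minus$unit,
              x$fit_dox_minus$ci[1], x$fit_dox_minus$ci[2]))
  cat(sprintf("  CIs overlap (growth indifferent to dox): %s\n",
              x$ci_overlap))
  invisible(x)
}

#' @export
tidy.growth_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$fit_dox_plus), condition = "dox_plus"),
    dplyr::mutate(glance(x$fit_dox_minus), condition = "dox_minus")
  ) |>
    dplyr::mutate(ci_overlap = x$ci_overlap) |>
    dplyr::relocate("condition")
}
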