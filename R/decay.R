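#' Conventional per-aliquot cell-number correction
#'
#' In the conventional chase design the control transcript scales with cell
#' number, so the normalized quantity of an aliquot sacrificed at time t is
#' diluted by the interval growth. Multiplying each quantity by `C_t / C_0`
#' (aliquot cell count over calibrator cell count) undoes the dilution, after
#' which the fitted decay constant estimates the true `k` directly (`j = 0`
#' downstream).
#'
#' @param points Normalized points carrying a `cell_count` column (see
#'   [add_cell_counts()]).
#' @param c0 Cell count of the calibrator. Default: the mean count of the
#'   aliquot(s) at the shortest chase time.
#' @return `points` with corrected `quantity`; counts metadata preserved.
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   aliquot_id = c("a0", "a1"), chase_time = c(0, 6), time_unit = "h",
#'   quantity = c(1, 0.25), cell_count = c(1e6, 2e6)
#' )
#' correct_conventional(pts)$quantity # 1, 0.5
correct_conventional <- function(points, c0 = NULL) {
  .require_columns(points, c("chase_time", "quantity"), "normalized points")
  if (!"cell_count" %in% names(points) || anyNA(points$cell_count)) {
    missing <- if ("cell_count" %in% names(points)) {
      points$aliquot_id[is.na(points$cell_count)]
    } else points$aliquot_id
    stop("conventional correction needs a cell_count on every point; ",
         "missing for: ", paste(missing %||% "<all>", collapse = ", "),
         call. = FALSE)
  }
  if (is.null(c0)) {
    c0 <- mean(points$cell_count[points$chase_time == min(points$chase_time)])
  }
  stopifnot(is.numeric(c0), length(c0) == 1L, c0 > 0)
  dplyr::mutate(points, quantity = .data$quantity * .data$cell_count / c0)
}

#' Fit exponential decay to normalized chase points
#'
#' Models the normalized quantity as `q(t) = n0 * exp(-k t)` or, with a
#' background plateau term, `q(t) = plateau + (n0 - plateau) * exp(-k t)`.
#' Two methods:
#'
#' * `log_linear` (default): OLS of `ln(quantity)` on time. Deterministic,
#'   no starting values, exact on single-exponential data; the plateau term is
#'   not available. R-squared is reported on the log scale.
#' * `nonlinear`: damped (Levenberg-Marquardt) least squares on the linear
#'   scale, initialized from the log-linear fit (plateau start =
#'   `min(quantity)/2` when requested). R-squared on the linear scale.
#'   A negative fitted plateau is clamped: the model is refit with the
#'   plateau fixed at 0 and the result flagged (`plateau_clamped`).
#'
#' @param points Normalized points (`chase_time`, `quantity` > 0, optionally
#'   `time_unit`); at least 3 points, 4 with a plateau. Duplicate chase times
#'   (replicates) are allowed.
#' @param method `"log_linear"` or `"nonlinear"`.
#' @param with_plateau Fit the background plateau term? Requires
#'   `method = "nonlinear"`.
#' @param unit Time unit; taken from the `time_unit` column when present.
#' @param max_iter Iteration cap for the nonlinear fit (default 200).
#' @return A `decay_fit` object: `k`, `n0`, `plateau` (`NA` when absent),
#'   `r_squared`, `scale_of_r2`, `method`, `unit`, `n_points`,
#'   `plateau_clamped`, the data, and the underlying fit. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' t <- seq(0, 120, 5)
#' pts <- tibble::tibble(chase_time = t, quantity = exp(-0.0338 * t))
#' fit_decay(pts, unit = "min")$k # 0.0338
fit_decay <- function(points, method = c("log_linear", "nonlinear"),
                      with_plateau = FALSE, unit = NULL, max_iter = 200L) {
  method <- match.arg(method)
  if (with_plateau && method != "nonlinear") {
    stop("the plateau term requires method = \"nonlinear\"", call. = FALSE)
  }
  .require_columns(points, c("chase_time", "quantity"), "normalized points")
  if ("time_unit" %in% names(points)) {
    unit <- unit %||% .one_unit(points$time_unit)
  }
  unit <- .check_unit(unit %||% stop("`unit` is required when points have ",
                                     "no time_unit column", call. = FALSE))
  if (any(points$quantity <= 0)) {
    stop("quantities must be positive", call. = FALSE)
  }
  n_min <- if (with_plateau) 4L else 3L
  if (nrow(points) < n_min) {
    stop("need at least ", n_min, " points for this fit", call. = FALSE)
  }

  t <- points$chase_time
  q <- points$quantity

  loglin <- lm(log(q) ~ t)
  k0 <- -unname(coef(loglin)[["t"]])
  n00 <- exp(unname(coef(loglin)[["(Intercept)"]]))

  if (method == "log_linear") {
    res <- list(k = k0, n0 = n00, plateau = NA_real_,
                r_squared = suppressWarnings(summary(loglin)$r.squared),
                scale_of_r2 = "log", fit = loglin, clamped = FALSE)
  } else {
    res <- .fit_decay_nls(t, q, k0, n00, with_plateau, max_iter)
  }

  structure(
    list(
      k = res$k, n0 = res$n0, plateau = res$plateau,
      r_squared = res$r_squared, scale_of_r2 = res$scale_of_r2,
      method = method, unit = unit, n_points = length(t),
      plateau_clamped = res$clamped,
      data = tibble::tibble(chase_time = t, quantity = q),
      fit = res$fit
    ),
    class = "decay_fit"
  )
}

.fit_decay_nls <- function(t, q, k0, n00, with_plateau, max_iter) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = max_iter)
  clamped <- FALSE
  if (with_plateau) {
    start <- list(plateau = min(q) / 2, n0 = n00, k = max(k0, 1e-8))
    fit <- minpack.lm::nlsLM(
      q ~ plateau + (n0 - plateau) * exp(-k * t),
      start = start, control = ctrl)
    if (coef(fit)[["plateau"]] < 0) {
      clamped <- TRUE
      fit <- minpack.lm::nlsLM(q ~ n0 * exp(-k * t),
                               start = list(n0 = n00, k = max(k0, 1e-8)),
                               control = ctrl)
    }
  } else {
    fit <- minpack.lm::nlsLM(q ~ n0 * exp(-k * t),
                             start = list(n0 = n00, k = max(k0, 1e-8)),
                             control = ctrl)
  }
  if (fit$convInfo$isConv == FALSE && fit$convInfo$stopCode == 9) {
    stop("nonlinear decay fit did not converge within ", max_iter,
         " iterations; last iterate: ",
         paste(sprintf("%s = %.6g", names(coef(fit)), coef(fit)),
               collapse = ", "), call. = FALSE)
  }
  cf <- coef(fit)
  plateau <- if (with_plateau && !clamped) cf[["plateau"]] else NA_real_
  pred <- predict(fit)
  list(k = cf[["k"]], n0 = cf[["n0"]], plateau = plateau,
       r_squared = 1 - sum((q - pred)^2) / sum((q - mean(q))^2),
       scale_of_r2 = "linear", fit = fit, clamped = clamped)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential decay fit (%s, %d points)\n  k = %.6g per %s,  n0 = %.4g%s\n  R-squared (%s scale) = %.4f\n",
    x$method, x$n_points, x$k, x$unit, x$n0,
    if (is.finite(x$plateau)) sprintf(",  plateau = %.4g", x$plateau) else "",
    x$scale_of_r2, x$r_squared))
  if (x$plateau_clamped) {
    cat("  note: negative fitted plateau clamped to 0 and refit\n")
  }
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  terms <- c("k", "n0", if (is.finite(x$plateau)) "plateau")
  tibble::tibble(term = terms,
                 estimate = c(x$k, x$n0,
                              if (is.finite(x$plateau)) x$plateau))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, n0 = x$n0, plateau = x$plateau, r.squared = x$r_squared,
    r2.scale = x$scale_of_r2, method = x$method, nobs = x$n_points,
    unit = x$unit
  )
}

#' @export
augment.decay_fit <- function(x, ...) {
  dplyr::mutate(x$data,
                .fitted = .predict_decay(x, .data$chase_time),
                .resid = .data$quantity - .data$.fitted)
}

.predict_decay <- function(fit, t) {
  p <- if (is.finite(fit$plateau)) fit$plateau else 0
  p + (fit$n0 - p) * exp(-fit$k * t)
}

#' Growth-corrected mRNA half-life
#'
#' The fitted decay constant `k` of the normalized quantities overstates the
#' true decay rate by the culture expansion constant `j` (growth dilutes the
#' per-cell control-normalized signal). The corrected half-life is
#' `t1/2 = ln(2) / (k - j)`. For conventional-design data already corrected
#' per aliquot, pass `j = 0`.
#'
#' @param k Fitted decay constant (per `unit`); may also be a [fit_decay()]
#'   object, in which case its `k` and unit are used.
#' @param j Expansion constant (per `unit`); may also be a [fit_expansion()]
#'   object. Default 0.
#' @param unit Time unit of both rates (required when `k` is a bare number
#'   and `j` carries no unit).
#' @param design Which chase design produced `k`: `"conventional"` (counts
#'   already applied, `j = 0`) or `"reverse_chase"`. Defaults to
#'   `"reverse_chase"` when `j > 0`, else `"conventional"`.
#' @return A `half_life_result`: `design`, `k`, `j`, `k_minus_j`,
#'   `half_life`, `unit`. `tidy()` returns the one-row table-style report.
#' @export
#' @examples
#' half_life(0.0414, 0.0224, unit = "h")$half_life  # 36.5 h
#' half_life(0.0338, 0.0004, unit = "min")$half_life # 20.7 min
half_life <- function(k, j = 0, unit = NULL, design = NULL) {
  if (inherits(k, "decay_fit")) {
    unit <- unit %||% k$unit
    k <- k$k
  }
  if (inherits(j, "growth_fit")) {
    if (!is.null(unit) && j$unit != unit) {
      stop(sprintf("unit mismatch: k is per %s but j is per %s", unit,
                   j$unit), call. = FALSE)
    }
    unit <- unit %||% j$unit
    j <- j$j
  }
  unit <- .check_unit(unit %||% stop("`unit` is required", call. = FALSE))
  stopifnot(is.numeric(k), is.numeric(j), length(k) == 1L, length(j) == 1L)
  if (k <= j) {
    stop(sprintf(
      "k (%.6g) <= j (%.6g): at this precision the mRNA appears infinitely stable or accumulating; no finite half-life",
      k, j), call. = FALSE)
  }
  design <- design %||% if (j > 0) "reverse_chase" else "conventional"
  design <- match.arg(design, c("conventional", "reverse_chase"))
  structure(
    list(design = design, k = k, j = j, k_minus_j = k - j,
         half_life = log(2) / (k - j), unit = unit),
    class = "half_life_result"
  )
}

#' @export
print.half_life_result <- function(x, ...) {
  cat(sprintf(
    "mRNA half-life (%s design)\n  j = %.4f  k = %.4f  k-j = %.4f  t1/2 = %.1f %s\n",
    x$design, x$j, x$k, x$k_minus_j, x$half_life, x$unit))
  invisible(x)
}

#' @export
tidy.half_life_result <- function(x, ...) {
  tibble::tibble(design = x$design, j = x$j, k = x$k,
                 k_minus_j = x$k_minus_j, half_life = x$half_life,
                 unit = x$unit)
}

#' Apparent half-life of a transcript when growth is ignored
#'
#' Without cell-number correction, the fitted constant is `k_true + j`, so
#' the apparent half-life obeys the harmonic identity
#' `1/t_apparent = 1/t_true + 1/t_doubling`. An infinitely stable transcript
#' thus appears to decay with a half-life equal to the culture doubling time.
#'
#' @param true_half_life True half-life (same time unit as `doubling_time`);
#'   `Inf` for an infinitely stable transcript.
#' @param doubling_time Culture doubling time; `Inf` for growth-arrested
#'   cells.
#' @return The apparent (uncorrected) half-life.
#' @export
#' @examples
#' apparent_half_life(Inf, 6) # 6
#' apparent_half_life(6, 6)   # 3
apparent_half_life <- function(true_half_life, doubling_time) {
  stopifnot(all(true_half_life > 0), all(doubling_time > 0))
  k_true <- ifelse(is.infinite(true_half_life), 0, log(2) / true_half_life)
  j <- ifelse(is.infinite(doubling_time), 0, log(2) / doubling_time)
  if (any(k_true + j == 0)) return(Inf)
  log(2) / (k_true + j)
}

#' End-to-end half-life estimate for one chase dataset
#'
#' Runs the design-appropriate correction and fit on a normalized-points
#' table and returns the corrected half-life:
#'
#' * `conventional`: per-aliquot cell-count correction
#'   ([correct_conventional()]), then [fit_decay()], then `t1/2 = ln(2)/k`
#'   (`j = 0`);
#' * `reverse_chase`: [fit_decay()] on the raw normalized points, then
#'   `t1/2 = ln(2)/(k - j)` with `j` from the growth fit.
#'
#' @param points Normalized points from [delta_delta_ct()]; for the
#'   conventional design they must carry `cell_count` (or pass `counts`).
#' @param design `"conventional"` or `"reverse_chase"`.
#' @param growth A [fit_expansion()] object, or a bare `j` value in the
#'   points' time unit (reverse-chase only).
#' @param counts Optional counts table joined via [add_cell_counts()]
#'   (conventional only).
#' @param c0 Calibrator cell count override (conventional only).
#' @param method,with_plateau Passed to [fit_decay()].
#' @return A `half_life_result` with the `decay_fit` attached as attribute
#'   `"fit"`.
#' @export
estimate_half_life <- function(points,
                               design = c("reverse_chase", "conventional"),
                               growth = NULL, counts = NULL, c0 = NULL,
                               method = c("log_linear", "nonlinear"),
                               with_plateau = FALSE) {
  design <- match.arg(design)
  method <- match.arg(method)
  unit <- if ("time_unit" %in% names(points)) .one_unit(points$time_unit)
          else NULL

  if (design == "conventional") {
    if (!is.null(counts)) points <- add_cell_counts(points, counts)
    points <- correct_conventional(points, c0 = c0)
    fit <- fit_decay(points, method = method, with_plateau = with_plateau,
                     unit = unit)
    res <- half_life(fit$k, 0, unit = fit$unit, design = "conventional")
  } else {
    if (is.null(growth)) {
      stop("reverse_chase estimation needs `growth` (a growth_fit or a ",
           "j value)", call. = FALSE)
    }
    j <- if (inherits(growth, "growth_fit")) {
      if (!is.null(unit) && growth$unit != unit) {
        stop(sprintf(
          "unit mismatch: chase times are in %s but j is per %s; convert with convert_rate()",
          unit, growth$unit), call. = FALSE)
      }
      growth$j
    } else {
      as.numeric(growth)
    }
    fit <- fit_decay(points, method = method, with_plateau = with_plateau,
                     unit = unit)
    res <- half_life(fit$k, j, unit = fit$unit, design = "reverse_chase")
  }
  attr(res, "fit") <- fit
  res
}
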