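#' Validate chase input tables
#'
#' Schema and sanity checks on a raw Ct table and (optionally) a cell-count
#' table before analysis. Findings are split into `fatal` (analysis cannot
#' proceed: missing columns, mixed units, non-positive counts, unreadable
#' file) and `warning` (analysis proceeds with exclusions: aliquots below
#' the 2-replicate minimum, undetected wells).
#'
#' @param ct_path Path to a Ct table ([read_ct_table()] schema).
#' @param counts_path Optional path to a count table.
#' @return A tibble of findings: `severity` (`"fatal"`/`"warning"`), `table`,
#'   `message`. Zero rows means a clean bill of health.
#' @export
validate_tables <- function(ct_path, counts_path = NULL) {
  findings <- list()
  note <- function(severity, table, message) {
    findings[[length(findings) + 1L]] <<-
      tibble::tibble(severity = severity, table = table, message = message)
  }

  ct <- tryCatch(read_ct_table(ct_path), error = function(e) {
    note("fatal", "ct", conditionMessage(e))
    NULL
  })
  if (!is.null(ct)) {
    undetected <- sum(is.na(ct$ct))
    if (undetected) {
      note("warning", "ct",
           sprintf("%d undetected well(s) (missing Ct)", undetected))
    }
    reps <- ct |>
      dplyr::filter(is.finite(.data$ct)) |>
      dplyr::count(.data$aliquot_id, .data$gene_role) |>
      dplyr::filter(.data$n < 2L)
    for (i in seq_len(nrow(reps))) {
      note("warning", "ct",
           sprintf("aliquot %s has only %d %s replicate(s) (minimum 2)",
                   reps$aliquot_id[i], reps$n[i], reps$gene_role[i]))
    }
    if (!any(ct$chase_time == min(ct$chase_time))) {
      note("fatal", "ct", "no calibrator aliquot")  # unreachable guard
    }
  }

  if (!is.null(counts_path)) {
    counts <- tryCatch(.read_delimited(counts_path), error = function(e) {
      note("fatal", "counts", conditionMessage(e))
      NULL
    })
    if (!is.null(counts)) {
      missing <- setdiff(c("time", "time_unit", "count"), names(counts))
      # simulator count tables carry chase_time instead of time
      if ("chase_time" %in% names(counts)) {
        missing <- setdiff(missing, "time")
      }
      if (length(missing)) {
        note("fatal", "counts", paste("missing required column(s):",
                                      paste(missing, collapse = ", ")))
      } else {
        if (any(counts$count <= 0, na.rm = TRUE)) {
          note("fatal", "counts", "non-positive cell count")
        }
        if (length(unique(counts$time_unit)) > 1L) {
          note("fatal", "counts", "mixed time units")
        }
      }
    }
  }

  if (length(findings)) dplyr::bind_rows(findings) else {
    tibble::tibble(severity = character(), table = character(),
                   message = character())
  }
}

#' Run the full chase analysis pipeline
#'
#' Executes load -> validate -> censor -> delta-delta-Ct -> (conventional
#' per-aliquot correction | nothing) -> decay fit -> growth-corrected
#' half-life, then writes a JSON report, a text summary mirroring the
#' j / k / k-j / t1/2 report layout, and a plot of the points with the fitted
#' curve.
#'
#' @param config A named list or the path to a flat YAML file with keys:
#'   `design` (`"conventional"`/`"reverse_chase"`), `ct` (Ct table path),
#'   `counts` (count table path; conventional only), `j` (numeric expansion
#'   constant) or `growth` (path to a cell-count series from which `j` is
#'   fitted), `calibrator_time` (optional), `method`
#'   (`"log_linear"`/`"nonlinear"`), `plateau` (logical),
#'   `censor_threshold` (cycles), `efficiency`, `out` (output directory;
#'   optional — nothing is written when absent).
#' @return The `half_life_result`, invisibly, with the decay fit in
#'   attribute `"fit"` and the report list in attribute `"report"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$design), !is.null(config$ct))
  design <- match.arg(config$design, c("conventional", "reverse_chase"))
  method <- match.arg(config$method %||% "log_linear",
                      c("log_linear", "nonlinear"))

  findings <- validate_tables(config$ct,
                              if (design == "conventional") config$counts)
  if (any(findings$severity == "fatal")) {
    stop("validation failed:\n",
         paste0("  [", findings$table, "] ", findings$message,
                collapse = "\n"), call. = FALSE)
  }

  ct <- read_ct_table(config$ct)
  unit <- .one_unit(ct$time_unit)

  growth_fit <- NULL
  j <- NULL
  if (design == "reverse_chase") {
    if (!is.null(config$growth)) {
      series <- read_count_table(config$growth)
      if (.one_unit(series$time_unit, "series") != unit) {
        stop(sprintf(
          "unit mismatch: chase times are in %s but growth series is in %s",
          unit, unique(series$time_unit)), call. = FALSE)
      }
      growth_fit <- fit_expansion(series)
      j <- growth_fit$j
    } else if (!is.null(config$j)) {
      j <- as.numeric(config$j)
    } else {
      stop("reverse_chase config needs `j` or `growth`", call. = FALSE)
    }
  }

  pts <- delta_delta_ct(ct,
                        calibrator_time = config$calibrator_time,
                        efficiency = config$efficiency %||% 2,
                        censor_threshold = config$censor_threshold %||% 0.5)

  counts <- NULL
  if (design == "conventional") {
    if (is.null(config$counts)) {
      stop("conventional config needs `counts`", call. = FALSE)
    }
    counts <- .read_delimited(config$counts)
    .require_columns(counts, c("aliquot_id", "count"), config$counts)
  }

  res <- estimate_half_life(pts, design = design,
                            growth = j, counts = counts,
                            method = method,
                            with_plateau = isTRUE(config$plateau))
  fit <- attr(res, "fit")

  report <- list(
    design = res$design, unit = res$unit,
    j = res$j, k = res$k, k_minus_j = res$k_minus_j,
    half_life = res$half_life,
    half_life_rounded = round(res$half_life, 1),
    method = fit$method, r_squared = fit$r_squared,
    r2_scale = fit$scale_of_r2,
    plateau = if (is.finite(fit$plateau)) fit$plateau else NULL,
    n_points = fit$n_points,
    n_aliquots_excluded = length(unique(ct$aliquot_id)) - nrow(pts)
  )
  attr(res, "report") <- report

  if (!is.null(config$out)) {
    if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out, "half_life.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(.format_report(report),
               file.path(config$out, "half_life.txt"))
    p <- autoplot(fit)
    ggplot2::ggsave(file.path(config$out, "decay_fit.pdf"), p,
                    width = 6, height = 4)
  }
  invisible(res)
}

# Text summary mirroring the j / k / k-j / t1/2 report layout.
.format_report <- function(r) {
  c(sprintf("design      %s", r$design),
    sprintf("method      %s", r$method),
    sprintf("j           %.4f per %s", r$j, r$unit),
    sprintf("k           %.4f per %s", r$k, r$unit),
    sprintf("k-j         %.4f per %s", r$k_minus_j, r$unit),
    sprintf("t1/2        %.1f %s", r$half_life, r$unit),
    sprintf("R-squared   %.4f (%s scale)", r$r_squared, r$r2_scale))
}
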