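#' Read a raw Ct table
#'
#' Reads a delimited text file (comma or tab, auto-detected) of threshold-cycle
#' readings from an RT-qPCR chase experiment. The file must carry the header
#' `aliquot_id, chase_time, time_unit, gene_role, replicate, ct`, with
#' `time_unit` in `{min, h}` (identical across the file) and `gene_role` in
#' `{study, control}`. Undetected wells are encoded as empty fields or `NA`,
#' never as a sentinel Ct.
#'
#' @param path Path to the delimited file.
#' @return A tibble with columns `aliquot_id` (character), `chase_time`
#'   (double), `time_unit` (character), `gene_role` (character), `replicate`
#'   (integer), `ct` (double; `NA` for undetected wells).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' sim <- simulate_chase(
#'   chase_design("reverse_chase", c(0, 30, 60), unit = "min"),
#'   truth_params(half_life = 30, j = 0, unit = "min"),
#'   noise_model(ct_sd = 0, seed = 1)
#' )
#' readr::write_csv(sim$ct, tf)
#' read_ct_table(tf)
read_ct_table <- function(path) {
  tab <- .read_delimited(path)
  required <- c("aliquot_id", "chase_time", "time_unit", "gene_role",
                "replicate", "ct")
  .require_columns(tab, required, path)
  tab <- dplyr::mutate(
    tab,
    aliquot_id = as.character(.data$aliquot_id),
    chase_time = as.double(.data$chase_time),
    time_unit  = as.character(.data$time_unit),
    gene_role  = as.character(.data$gene_role),
    replicate  = as.integer(.data$replicate),
    ct         = suppressWarnings(as.double(.data$ct))
  )
  .one_unit(tab$time_unit)
  bad_role <- setdiff(unique(tab$gene_role), c("study", "control"))
  if (length(bad_role)) {
    stop("gene_role must be 'study' or 'control'; found: ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  if (any(tab$chase_time < 0, na.rm = TRUE)) {
    stop("chase_time must be non-negative", call. = FALSE)
  }
  if (any(is.finite(tab$ct) & tab$ct <= 0)) {
    stop("detected wells must have ct > 0; undetected wells must be NA",
         call. = FALSE)
  }
  tibble::as_tibble(tab[required])
}

# Sniff comma vs tab from the header line; readr does the rest.
.read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

.require_columns <- function(tab, required, path) {
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(tab)
}

#' Censor an outlying technical replicate
#'
#' qPCR assays are run in technical triplicate; occasionally one well's Ct is
#' discordant (pipetting error, evaporation). Given 2-3 Ct values from one
#' well group, drops at most one: the value farthest from the median is
#' removed iff its absolute deviation from the median of the remaining values
#' exceeds `threshold` cycles. Pairs are always retained, so censoring is
#' idempotent.
#'
#' @param ct Numeric vector of 2-3 finite Ct values.
#' @param threshold Censoring threshold in cycles (default 0.5).
#' @return The retained Ct values (input order preserved).
#' @export
#' @examples
#' censor_ct(c(20.1, 20.2, 23.0)) # drops 23.0
#' censor_ct(c(20.1, 20.2, 20.3)) # keeps all
censor_ct <- function(ct, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold > 0)
  if (length(ct) < 2L) {
    stop("censoring needs at least 2 Ct values; got ", length(ct),
         call. = FALSE)
  }
  if (length(ct) > 3L) {
    stop("censoring is defined for 2-3 technical replicates; got ",
         length(ct), call. = FALSE)
  }
  if (!all(is.finite(ct))) {
    stop("censoring requires finite Ct values; drop undetected wells first",
         call. = FALSE)
  }
  ct[.censor_keep(ct, threshold)]
}

# Logical keep-mask used both by censor_ct() and the grouped pipeline.
.censor_keep <- function(ct, threshold) {
  keep <- rep(TRUE, length(ct))
  if (length(ct) != 3L) return(keep)
  cand <- which.max(abs(ct - median(ct)))
  others <- ct[-cand]
  if (abs(ct[cand] - median(others)) > threshold) keep[cand] <- FALSE
  keep
}

#' Relative quantitation of a chase time course by the delta-delta-Ct method
#'
#' Converts raw Ct wells into one normalized relative quantity per aliquot.
#' Per aliquot, `dCt = mean(ct study) - mean(ct control)`; against the
#' calibrator aliquot (by default the one with the shortest chase time,
#' normally 0), `ddCt = dCt - dCt_calibrator` and
#' `quantity = efficiency^(-ddCt)`. With perfect amplification efficiency
#' (2.0 per cycle, the standard assumption) this is `2^(-ddCt)`. When several
#' aliquots sit at the calibrator time, the mean of their dCt values is the
#' calibrator dCt.
#'
#' Undetected wells (`NA` Ct) are dropped before censoring. Aliquots that end
#' with fewer than 2 retained study or control replicates are excluded with a
#' warning naming them; a missing calibrator is an error.
#'
#' @param data Ct table as returned by [read_ct_table()] or
#'   [simulate_chase()]: columns `aliquot_id`, `chase_time`, `time_unit`,
#'   `gene_role`, `replicate`, `ct`.
#' @param calibrator_time Chase time of the calibrator aliquot. Default:
#'   the shortest chase time present.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @param censor Apply [censor_ct()] per aliquot and gene role first?
#'   Default `TRUE`.
#' @param censor_threshold Threshold in cycles passed to the censoring rule.
#' @return A tibble of normalized points, one row per retained aliquot:
#'   `aliquot_id`, `chase_time`, `time_unit`, `quantity`, `n_study`,
#'   `n_control`, sorted by chase time. The calibrator's quantity is exactly 1
#'   (when it is a single aliquot).
#' @export
#' @examples
#' sim <- simulate_chase(
#'   chase_design("reverse_chase", seq(0, 100, 20), unit = "min"),
#'   truth_params(half_life = 30, j = 0.0004, unit = "min"),
#'   noise_model(ct_sd = 0, seed = 7)
#' )
#' delta_delta_ct(sim$ct)
delta_delta_ct <- function(data, calibrator_time = NULL, efficiency = 2,
                           censor = TRUE, censor_threshold = 0.5) {
  stopifnot(is.numeric(efficiency), length(efficiency) == 1L, efficiency > 1)
  .require_columns(data, c("aliquot_id", "chase_time", "time_unit",
                           "gene_role", "replicate", "ct"), "Ct table")
  unit <- .one_unit(data$time_unit)

  wells <- dplyr::filter(data, is.finite(.data$ct))
  if (censor) {
    wells <- wells |>
      dplyr::group_by(.data$aliquot_id, .data$gene_role) |>
      dplyr::filter(dplyr::n() < 2L |
                      .censor_keep(.data$ct, .env$censor_threshold)) |>
      dplyr::ungroup()
  }

  per_role <- wells |>
    dplyr::group_by(.data$aliquot_id, .data$chase_time, .data$gene_role) |>
    dplyr::summarise(mean_ct = mean(.data$ct), n = dplyr::n(),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene_role",
                       values_from = c("mean_ct", "n"),
                       names_sep = "_")
  for (col in c("mean_ct_study", "mean_ct_control", "n_study", "n_control")) {
    if (!col %in% names(per_role)) per_role[[col]] <- NA_real_
  }
  per_role <- dplyr::mutate(
    per_role,
    n_study   = dplyr::coalesce(as.integer(.data$n_study), 0L),
    n_control = dplyr::coalesce(as.integer(.data$n_control), 0L)
  )

  low <- dplyr::filter(per_role, .data$n_study < 2L | .data$n_control < 2L)
  if (nrow(low)) {
    warning("excluding aliquot(s) with < 2 retained study or control ",
            "replicates: ", paste(low$aliquot_id, collapse = ", "),
            call. = FALSE)
    per_role <- dplyr::anti_join(per_role, low, by = "aliquot_id")
  }
  if (!nrow(per_role)) stop("no aliquot passed the replicate minimum",
                            call. = FALSE)

  per_role <- dplyr::mutate(
    per_role, d_ct = .data$mean_ct_study - .data$mean_ct_control)

  calibrator_time <- calibrator_time %||% min(per_role$chase_time)
  cal <- dplyr::filter(per_role, .data$chase_time == calibrator_time)
  if (!nrow(cal)) {
    stop("no calibrator aliquot at chase_time = ", calibrator_time,
         call. = FALSE)
  }

  per_role |>
    dplyr::mutate(
      quantity  = efficiency^(-(.data$d_ct - mean(cal$d_ct))),
      time_unit = unit
    ) |>
    dplyr::arrange(.data$chase_time, .data$aliquot_id) |>
    dplyr::select("aliquot_id", "chase_time", "time_unit", "quantity",
                  "n_study", "n_control")
}

#' Attach per-aliquot cell counts to normalized points
#'
#' Joins a counts table (columns `aliquot_id`, `count`) onto a
#' normalized-points table by `aliquot_id`, as required by the conventional
#' design's cell-number correction.
#'
#' @param points Normalized points from [delta_delta_ct()].
#' @param counts Tibble with `aliquot_id` and `count` columns (e.g. the
#'   `counts` element of [simulate_chase()] output, or [read_count_table()]
#'   output carrying aliquot ids).
#' @return `points` with a `cell_count` column.
#' @export
add_cell_counts <- function(points, counts) {
  .require_columns(counts, c("aliquot_id", "count"), "counts table")
  out <- dplyr::left_join(
    points,
    dplyr::select(counts, "aliquot_id", cell_count = "count"),
    by = "aliquot_id")
  if (anyNA(out$cell_count)) {
    stop("no cell count for aliquot(s): ",
         paste(out$aliquot_id[is.na(out$cell_count)], collapse = ", "),
         call. = FALSE)
  }
  out
}
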