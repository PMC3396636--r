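#' Describe a chase experiment design
#'
#' A design is the schedule of chase durations (antibiotic-to-sacrifice
#' intervals) plus replication. In the conventional design every aliquot
#' receives antibiotic at t = 0 and is sacrificed after its duration; in the
#' reverse chase every aliquot is sacrificed at the common end time and
#' receives antibiotic `duration` before it. The zero-duration aliquot is the
#' calibrator and must be present.
#'
#' @param kind `"conventional"` or `"reverse_chase"`.
#' @param timepoints Strictly increasing non-negative chase durations,
#'   including 0.
#' @param unit Time unit, `"min"` or `"h"`.
#' @param replicates Independent biological replicates (default 1).
#' @param tech_reps qPCR technical replicates per well group (default 3).
#' @return A `chase_design` list.
#' @export
chase_design <- function(kind = c("conventional", "reverse_chase"),
                         timepoints, unit, replicates = 1L, tech_reps = 3L) {
  kind <- match.arg(kind)
  unit <- .check_unit(unit)
  if (length(timepoints) < 1L) stop("timepoints must be non-empty",
                                    call. = FALSE)
  if (any(timepoints < 0) || any(diff(timepoints) <= 0)) {
    stop("timepoints must be strictly increasing and non-negative",
         call. = FALSE)
  }
  if (!0 %in% timepoints) {
    stop("timepoints must include 0 (the calibrator aliquot)", call. = FALSE)
  }
  stopifnot(replicates >= 1L, tech_reps >= 1L)
  structure(list(kind = kind, timepoints = as.double(timepoints),
                 unit = unit, replicates = as.integer(replicates),
                 tech_reps = as.integer(tech_reps)),
            class = "chase_design")
}

#' Ground-truth parameters for a simulated chase
#'
#' @param half_life True half-life of the study mRNA (same unit as the
#'   design); `Inf` for an infinitely stable transcript.
#' @param j Culture expansion constant (per unit; default 0).
#' @param unit Time unit.
#' @param steady_state_quantity Steady-state study-mRNA level per cell at
#'   shutoff, arbitrary units (default 1).
#' @param plateau_fraction Fraction of the steady-state level maintained by
#'   background antibiotic-indifferent transcription, in `[0, 1)` (default 0).
#' @return A `truth_params` list (also carries `k_true = ln2/half_life`).
#' @export
truth_params <- function(half_life = Inf, j = 0, unit,
                         steady_state_quantity = 1, plateau_fraction = 0) {
  unit <- .check_unit(unit)
  stopifnot(half_life > 0, j >= 0, steady_state_quantity > 0,
            plateau_fraction >= 0, plateau_fraction < 1)
  structure(list(
    half_life = half_life,
    k_true = if (is.infinite(half_life)) 0 else log(2) / half_life,
    j = j, unit = unit,
    steady_state_quantity = steady_state_quantity,
    plateau_fraction = plateau_fraction
  ), class = "truth_params")
}

#' Measurement-noise model for simulated chases
#'
#' @param ct_sd Gaussian SD of Ct readings, cycles (default 0.15).
#' @param count_cv Coefficient of variation of the hemocytometer cell count,
#'   lognormal multiplicative error (default 0.10; conventional design only).
#' @param seeding_cv CV of the number of cells seeded per aliquot (default
#'   0.02).
#' @param seed RNG seed; simulation is reproducible given the seed.
#' @return A `noise_model` list.
#' @export
noise_model <- function(ct_sd = 0.15, count_cv = 0.10, seeding_cv = 0.02,
                        seed = 1L) {
  stopifnot(ct_sd >= 0, count_cv >= 0, seeding_cv >= 0)
  structure(list(ct_sd = ct_sd, count_cv = count_cv,
                 seeding_cv = seeding_cv, seed = as.integer(seed)),
            class = "noise_model")
}

# Mean-1 lognormal multiplicative error with the given CV.
.lognormal_error <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate a transcriptional chase experiment
#'
#' Mechanistic generative model shared by both designs:
#' cells in every aliquot grow exponentially, `C(t) = C_seed * exp(j t)`,
#' indifferent to the antibiotic; the control mRNA signal is proportional to
#' cell number at sacrifice; the total study mRNA at sacrifice is
#' proportional to the cell number at shutoff times
#' `plateau_fraction + (1 - plateau_fraction) * exp(-k_true * d)` for chase
#' duration `d`. Ct values are back-computed as
#' `ct = ref - log2(signal) + N(0, ct_sd)` per technical replicate.
#' Conventional aliquots additionally report a cell count at sacrifice with
#' lognormal error (`count_cv`).
#'
#' Under this model the noiseless normalized quantity at duration `d` equals
#' `exp(-(k_true + j) d)` in **both** designs (reverse chase: late shutoff
#' means the calibrator's study pool was made in fewer cells; conventional:
#' the control pool keeps growing), which is why the fitted constant must be
#' corrected by `j`.
#'
#' @param design A [chase_design()].
#' @param truth A [truth_params()] (unit must match the design).
#' @param noise A [noise_model()].
#' @param seed_cells Cells seeded per aliquot (default 1e4).
#' @return A `chase_sim` list: `ct` (raw Ct table in the [read_ct_table()]
#'   schema), `counts` (conventional designs: tibble `aliquot_id`,
#'   `chase_time`, `time_unit`, `count`, plus hidden true counts in
#'   `true_count`; `NULL` for reverse chase), and `truth` (all generative
#'   parameters, including the design and noise).
#' @export
#' @examples
#' sim <- simulate_chase(
#'   chase_design("conventional", seq(0, 24, 6), unit = "h"),
#'   truth_params(half_life = Inf, j = log(2) / 6, unit = "h"),
#'   noise_model(ct_sd = 0, count_cv = 0, seeding_cv = 0)
#' )
#' delta_delta_ct(sim$ct) # quantity halves every 6 h: pure growth dilution
simulate_chase <- function(design, truth, noise = noise_model(),
                           seed_cells = 1e4) {
  stopifnot(inherits(design, "chase_design"), inherits(truth, "truth_params"),
            inherits(noise, "noise_model"))
  if (design$unit != truth$unit) {
    stop(sprintf("unit mismatch: design in %s, truth in %s", design$unit,
                 truth$unit), call. = FALSE)
  }
  set.seed(noise$seed)

  # Arbitrary instrument reference Cts; they cancel in the ddCt arithmetic.
  ref_study <- 22
  ref_control <- 16

  t_end <- max(design$timepoints)
  grid <- tidyr::expand_grid(rep = seq_len(design$replicates),
                             duration = design$timepoints)
  n_aliquots <- nrow(grid)

  c_seed <- seed_cells * .lognormal_error(n_aliquots, noise$seeding_cv)
  d <- grid$duration
  if (design$kind == "conventional") {
    c_shutoff <- c_seed
    c_sacrifice <- c_seed * exp(truth$j * d)
  } else {
    c_shutoff <- c_seed * exp(truth$j * (t_end - d))
    c_sacrifice <- c_seed * exp(truth$j * t_end)
  }
  decay_term <- truth$plateau_fraction +
    (1 - truth$plateau_fraction) * exp(-truth$k_true * d)
  study_signal <- truth$steady_state_quantity * c_shutoff * decay_term
  control_signal <- c_sacrifice

  aliquots <- tibble::tibble(
    aliquot_id = sprintf("r%d_t%s", grid$rep, format(d, trim = TRUE)),
    chase_time = d,
    ct_study = ref_study - log2(study_signal / seed_cells),
    ct_control = ref_control - log2(control_signal / seed_cells)
  )

  ct <- aliquots |>
    tidyr::pivot_longer(c("ct_study", "ct_control"),
                        names_to = "gene_role", names_prefix = "ct_",
                        values_to = "ct_base") |>
    tidyr::expand_grid(replicate = seq_len(design$tech_reps)) |>
    dplyr::mutate(
      time_unit = design$unit,
      ct = .data$ct_base + rnorm(dplyr::n(), 0, noise$ct_sd)
    ) |>
    dplyr::select("aliquot_id", "chase_time", "time_unit", "gene_role",
                  "replicate", "ct")

  counts <- NULL
  if (design$kind == "conventional") {
    counts <- tibble::tibble(
      aliquot_id = aliquots$aliquot_id,
      chase_time = d,
      time_unit = design$unit,
      count = c_sacrifice * .lognormal_error(n_aliquots, noise$count_cv),
      true_count = c_sacrifice
    )
  }

  structure(list(ct = ct, counts = counts,
                 truth = c(unclass(truth),
                           list(design = design, noise = noise,
                                seed_cells = seed_cells))),
            class = "chase_sim")
}

# One simulated experiment through the full analysis pipeline.
.analyze_sim <- function(sim, method = "log_linear", with_plateau = FALSE) {
  pts <- suppressWarnings(delta_delta_ct(sim$ct))
  design <- sim$truth$design$kind
  if (design == "conventional") {
    estimate_half_life(add_cell_counts(pts, sim$counts),
                       design = "conventional", method = method,
                       with_plateau = with_plateau)
  } else {
    estimate_half_life(pts, design = "reverse_chase", growth = sim$truth$j,
                       method = method, with_plateau = with_plateau)
  }
}

#' Monte-Carlo comparison of conventional and reverse-chase designs
#'
#' Simulates `n_sims` experiments per design from a shared truth, analyses
#' each through the full quantitation + estimation pipeline (conventional:
#' noisy per-aliquot counts; reverse chase: the true `j`), and summarises the
#' half-life estimates per design. Reporting only; asserts nothing.
#'
#' Per-simulation seeds derive from `noise$seed` by drawing `2 * n_sims`
#' child seeds with `sample.int()` under the master seed, so any individual
#' run can be reproduced in isolation.
#'
#' @param truth A [truth_params()] shared by both designs.
#' @param conv_design,rc_design [chase_design()] objects (kinds
#'   `"conventional"` and `"reverse_chase"`).
#' @param noise A [noise_model()]; its `seed` is the master seed.
#' @param n_sims Simulations per design (>= 2).
#' @return A tibble with one row per design: `design`, `n_sims`, `n_failed`,
#'   `mean_t_half`, `sd_t_half`, `median_abs_error`, `bias`,
#'   `mean_r_squared`, `true_t_half`. Per-simulation results are attached as
#'   attribute `"runs"`.
#' @export
compare_designs <- function(truth, conv_design, rc_design,
                            noise = noise_model(), n_sims = 200L) {
  stopifnot(n_sims >= 2L,
            conv_design$kind == "conventional",
            rc_design$kind == "reverse_chase")
  set.seed(noise$seed)
  child_seeds <- sample.int(.Machine$integer.max, 2L * n_sims)

  run_one <- function(design, seed) {
    ns <- noise
    ns$seed <- seed
    tryCatch({
      res <- .analyze_sim(simulate_chase(design, truth, ns))
      tibble::tibble(t_half = res$half_life,
                     r_squared = attr(res, "fit")$r_squared,
                     error = NA_character_)
    }, error = function(e) {
      tibble::tibble(t_half = NA_real_, r_squared = NA_real_,
                     error = conditionMessage(e))
    })
  }

  runs <- dplyr::bind_rows(
    purrr::map2_dfr(
      seq_len(n_sims), child_seeds[seq_len(n_sims)],
      function(i, s) dplyr::mutate(run_one(conv_design, s),
                                   design = "conventional", sim = i,
                                   seed = s)),
    purrr::map2_dfr(
      seq_len(n_sims), child_seeds[n_sims + seq_len(n_sims)],
      function(i, s) dplyr::mutate(run_one(rc_design, s),
                                   design = "reverse_chase", sim = i,
                                   seed = s))
  )

  summary <- runs |>
    dplyr::group_by(.data$design) |>
    dplyr::summarise(
      n_sims = dplyr::n(),
      n_failed = sum(!is.na(.data$error)),
      mean_t_half = mean(.data$t_half, na.rm = TRUE),
      sd_t_half = sd(.data$t_half, na.rm = TRUE),
      median_abs_error = median(abs(.data$t_half - truth$half_life),
                                na.rm = TRUE),
      bias = mean(.data$t_half - truth$half_life, na.rm = TRUE),
      mean_r_squared = mean(.data$r_squared, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(true_t_half = truth$half_life, unit = truth$unit)
  attr(summary, "runs") <- runs
  class(summary) <- c("design_comparison", class(summary))
  summary
}

#' Bundled demonstration scenarios
#'
#' Deterministic, fixed-seed small datasets used in tests and documentation.
#' Scenarios:
#'
#' * `fig1a`: conventional design, 5 timepoints over 24 h, infinitely stable
#'   study mRNA in cells doubling every 6 h, zero noise. The uncorrected
#'   globin:actin ratio decays with an apparent 6-h half-life — the artifact
#'   the growth correction exists to remove.
#' * `are_like`: reverse chase, 5-min spacing over 0-100 min, matching an
#'   AU-rich-element reporter with observed k = 0.0338 per min at
#'   j = 0.0004 per min (so true k = 0.0334 per min), noiseless.
#' * `wt_like`: reverse chase over 80 h (16 points), matching a wild-type
#'   globin reporter with observed k = 0.0414 per h at j = 0.0224 per h,
#'   noiseless.
#' * `plateau_demo`: reverse chase, growth-arrested culture (j = 0) with 10%
#'   background antibiotic-indifferent transcription, noiseless; exercises
#'   the plateau term of [fit_decay()].
#'
#' @param scenario One of `"fig1a"`, `"are_like"`, `"wt_like"`,
#'   `"plateau_demo"`.
#' @param dir Optional directory; when given, the Ct table (`<scenario>_ct.csv`),
#'   any counts table (`<scenario>_counts.csv`) and a `<scenario>_truth.json`
#'   sidecar of generative parameters are written there as delimited
#'   text/JSON.
#' @return The [simulate_chase()] result for the scenario (invisibly when
#'   `dir` is given).
#' @export
fixture_tables <- function(scenario, dir = NULL) {
  scenarios <- list(
    fig1a = function() simulate_chase(
      chase_design("conventional", seq(0, 24, 6), unit = "h"),
      truth_params(half_life = Inf, j = log(2) / 6, unit = "h"),
      noise_model(ct_sd = 0, count_cv = 0, seeding_cv = 0, seed = 101L)),
    are_like = function() simulate_chase(
      chase_design("reverse_chase", seq(0, 100, 5), unit = "min"),
      truth_params(half_life = log(2) / (0.0338 - 0.0004), j = 0.0004,
                   unit = "min"),
      noise_model(ct_sd = 0, count_cv = 0, seeding_cv = 0, seed = 102L)),
    wt_like = function() simulate_chase(
      chase_design("reverse_chase", round(seq(0, 80, length.out = 16), 3),
                   unit = "h"),
      truth_params(half_life = log(2) / (0.0414 - 0.0224), j = 0.0224,
                   unit = "h"),
      noise_model(ct_sd = 0, count_cv = 0, seeding_cv = 0, seed = 103L)),
    plateau_demo = function() simulate_chase(
      chase_design("reverse_chase", seq(0, 120, 10), unit = "min"),
      truth_params(half_life = log(2) / 0.03, j = 0, unit = "min",
                   plateau_fraction = 0.1),
      noise_model(ct_sd = 0, count_cv = 0, seeding_cv = 0, seed = 104L))
  )
  if (!scenario %in% names(scenarios)) {
    stop("unknown scenario '", scenario, "'; valid: ",
         paste(names(scenarios), collapse = ", "), call. = FALSE)
  }
  sim <- scenarios[[scenario]]()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(sim$ct, file.path(dir, paste0(scenario, "_ct.csv")))
    if (!is.null(sim$counts)) {
      readr::write_csv(sim$counts,
                       file.path(dir, paste0(scenario, "_counts.csv")))
    }
    truth <- sim$truth
    truth$design <- unclass(truth$design)
    truth$noise <- unclass(truth$noise)
    jsonlite::write_json(truth,
                         file.path(dir, paste0(scenario, "_truth.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(sim))
  }
  sim
}
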