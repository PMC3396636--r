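# Build a raw Ct table whose ddCt-normalized quantities equal `q` exactly
# (noiseless): study ct = base_study - log2(q), control ct constant.
ct_table_from_quantities <- function(times, q, unit = "min",
                                     base_study = 22, base_control = 16,
                                     reps = 3) {
  stopifnot(length(times) == length(q))
  tidyr::expand_grid(
    idx = seq_along(times),
    gene_role = c("study", "control"),
    replicate = seq_len(reps)
  ) |>
    dplyr::mutate(
      aliquot_id = sprintf("a%d", idx),
      chase_time = times[idx],
      time_unit = unit,
      ct = ifelse(gene_role == "study",
                  base_study - log2(q[idx]), base_control)
    ) |>
    dplyr::select(aliquot_id, chase_time, time_unit, gene_role, replicate, ct)
}

# Exponential count series, optionally with lognormal noise.
count_series <- function(j, c0 = 5e4, times = seq(0, 96, 12), unit = "h",
                         cv = 0, condition = "dox_plus") {
  noise <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    exp(rnorm(length(times), -sdlog^2 / 2, sdlog))
  } else 1
  tibble::tibble(time = times, time_unit = unit,
                 count = c0 * exp(j * times) * noise,
                 condition = condition)
}
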