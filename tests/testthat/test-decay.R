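test_that("per-aliquot cell-number correction multiplies by C_t/C_0", {
  pts <- tibble::tibble(
    aliquot_id = c("a0", "a1", "a2"), chase_time = c(0, 6, 12),
    time_unit = "h", quantity = c(1, 0.25, 0.1),
    cell_count = c(1e6, 2e6, 4e6))
  out <- correct_conventional(pts)
  expect_equal(out$quantity, c(1, 0.5, 0.4))
  expect_equal(out$cell_count, pts$cell_count) # metadata preserved

  # C_t = C_0 everywhere is the identity
  same <- dplyr::mutate(pts, cell_count = 1e6)
  expect_equal(correct_conventional(same)$quantity, pts$quantity)

  # infinitely stable mRNA: quantity halves as cells double; correction
  # restores a flat line at 1
  halving <- tibble::tibble(
    aliquot_id = paste0("a", 0:4), chase_time = seq(0, 24, 6),
    time_unit = "h", quantity = 2^-(0:4), cell_count = 1e6 * 2^(0:4))
  expect_equal(correct_conventional(halving)$quantity, rep(1, 5))

  expect_error(correct_conventional(dplyr::select(pts, -cell_count)),
               "cell_count")
})

test_that("both fitting methods are exact on noiseless single-exponential data", {
  t <- seq(0, 120, 5)
  pts <- tibble::tibble(chase_time = t, quantity = exp(-0.0338 * t))
  ll <- fit_decay(pts, unit = "min")
  nl <- fit_decay(pts, method = "nonlinear", unit = "min")
  expect_equal(ll$k, 0.0338, tolerance = 1e-10)
  expect_equal(nl$k, 0.0338, tolerance = 1e-8)
  expect_equal(ll$r_squared, 1)
  expect_equal(nl$r_squared, 1, tolerance = 1e-12)
  expect_equal(ll$k, nl$k, tolerance = 1e-8)
  expect_identical(ll$scale_of_r2, "log")
  expect_identical(nl$scale_of_r2, "linear")

  # constant quantities: slope collapses to 0
  flat <- tibble::tibble(chase_time = t, quantity = rep(2, length(t)))
  expect_equal(fit_decay(flat, unit = "min")$k, 0, tolerance = 1e-12)
})

test_that("the plateau term captures background transcription the log-linear fit cannot", {
  t <- seq(0, 200, 10)
  pts <- tibble::tibble(chase_time = t,
                        quantity = 0.05 + 0.95 * exp(-0.03 * t))
  with_p <- fit_decay(pts, method = "nonlinear", with_plateau = TRUE,
                      unit = "min")
  expect_equal(with_p$plateau, 0.05, tolerance = 1e-6)
  expect_equal(with_p$k, 0.03, tolerance = 1e-6)
  # ignoring the plateau biases k low (late points sit above the exponential)
  ll <- fit_decay(pts, unit = "min")
  expect_lt(ll$k, 0.03)
  expect_lt(ll$r_squared, 1 - 1e-4)
  expect_error(fit_decay(pts, method = "log_linear", with_plateau = TRUE),
               "nonlinear")
})

test_that("a negative fitted plateau is clamped to zero and flagged", {
  # super-exponential tail drives the unconstrained plateau negative
  t <- seq(0, 60, 5)
  q <- exp(-0.05 * t) * exp(-0.0005 * t^2)
  fit <- fit_decay(tibble::tibble(chase_time = t, quantity = q),
                   method = "nonlinear", with_plateau = TRUE, unit = "min")
  expect_true(fit$plateau_clamped)
  expect_true(is.na(fit$plateau))
})

test_that("growth-corrected half-life reproduces all six reported replicates", {
  # j, k, k-j, t1/2 for three short-lived (min) and three long-lived (h)
  # reporter replicates
  rows <- tibble::tribble(
    ~j,      ~k,      ~t_half, ~unit,
    0.0004, 0.0338, 20.7,   "min",
    0.0004, 0.0353, 19.9,   "min",
    0.0004, 0.0369, 19.0,   "min",
    0.0224, 0.0414, 36.5,   "h",
    0.0224, 0.0425, 34.5,   "h",
    0.0224, 0.0464, 28.9,   "h"
  )
  for (i in seq_len(nrow(rows))) {
    res <- half_life(rows$k[i], rows$j[i], unit = rows$unit[i])
    expect_equal(res$k_minus_j, rows$k[i] - rows$j[i], tolerance = 1e-12)
    expect_lt(abs(res$half_life - rows$t_half[i]), 0.1)
    expect_equal(res$half_life, log(2) / (rows$k[i] - rows$j[i]))
  }
})

test_that("half-life refuses k <= j and honours the no-growth limit", {
  expect_error(half_life(0.02, 0.03, unit = "h"), "infinitely stable")
  expect_error(half_life(0.02, 0.02, unit = "h"), "infinitely stable")
  expect_equal(half_life(0.0338, 0, unit = "min")$half_life,
               log(2) / 0.0338)
  # accepts fitted objects and checks their units
  t <- seq(0, 100, 10)
  fit <- fit_decay(tibble::tibble(chase_time = t, quantity = exp(-0.04 * t)),
                   unit = "h")
  growth <- fit_expansion(count_series(0.0224), unit = "h")
  expect_equal(half_life(fit, growth)$half_life,
               log(2) / (0.04 - 0.0224), tolerance = 1e-6)
  growth_min <- fit_expansion(count_series(0.0004, times = seq(0, 120, 15),
                                           unit = "min"))
  expect_error(half_life(fit, growth_min), "unit mismatch")
})

test_that("half-life is monotone: increasing in j, decreasing in k", {
  js <- seq(0, 0.03, 0.005)
  hl_j <- vapply(js, function(j) half_life(0.04, j, unit = "h")$half_life,
                 numeric(1))
  expect_true(all(diff(hl_j) > 0))
  ks <- seq(0.03, 0.08, 0.01)
  hl_k <- vapply(ks, function(k) half_life(k, 0.02, unit = "h")$half_life,
                 numeric(1))
  expect_true(all(diff(hl_k) < 0))
})

test_that("apparent half-life follows the harmonic identity", {
  expect_equal(apparent_half_life(Inf, 6), 6)
  expect_equal(apparent_half_life(6, 6), 3)
  expect_equal(apparent_half_life(6, Inf), 6)
  expect_equal(apparent_half_life(Inf, Inf), Inf)
  # 1/t_app = 1/t_true + 1/t_double for arbitrary values
  expect_equal(1 / apparent_half_life(8, 24), 1 / 8 + 1 / 24)
})

test_that("conventional and reverse-chase estimates agree on noiseless data", {
  truth <- truth_params(half_life = 20, j = 0.0004, unit = "min")
  quiet <- noise_model(ct_sd = 0, count_cv = 0, seeding_cv = 0, seed = 9)
  tp <- seq(0, 120, 10)
  conv <- simulate_chase(chase_design("conventional", tp, unit = "min"),
                         truth, quiet)
  rc <- simulate_chase(chase_design("reverse_chase", tp, unit = "min"),
                       truth, quiet)
  res_c <- estimate_half_life(
    add_cell_counts(delta_delta_ct(conv$ct), conv$counts),
    design = "conventional")
  res_r <- estimate_half_life(delta_delta_ct(rc$ct),
                              design = "reverse_chase", growth = 0.0004)
  expect_equal(res_c$half_life, 20, tolerance = 1e-8)
  expect_equal(res_r$half_life, res_c$half_life, tolerance = 1e-8)
  # fitted constant is the observed k_true + j; j lives in different slots
  expect_equal(res_r$k, log(2) / 20 + 0.0004, tolerance = 1e-8)
  expect_equal(res_c$j, 0)
  expect_equal(res_r$j, 0.0004)
})

test_that("estimate_half_life enforces design/unit consistency", {
  pts <- delta_delta_ct(fixture_tables("are_like")$ct) # minutes
  expect_error(estimate_half_life(pts, design = "reverse_chase"), "growth")
  growth_h <- fit_expansion(count_series(0.0224), unit = "h")
  expect_error(estimate_half_life(pts, design = "reverse_chase",
                                  growth = growth_h), "unit mismatch")
  expect_error(estimate_half_life(pts, design = "conventional"),
               "cell_count")
})

test_that("decay fit tidiers, augment and plot expose the fit", {
  t <- seq(0, 100, 10)
  fit <- fit_decay(tibble::tibble(chase_time = t, quantity = exp(-0.03 * t)),
                   unit = "min")
  expect_equal(tidy(fit)$estimate[tidy(fit)$term == "k"], fit$k)
  expect_equal(glance(fit)$r.squared, 1)
  aug <- augment(fit)
  expect_equal(aug$.resid, rep(0, length(t)), tolerance = 1e-10)
  expect_s3_class(autoplot(fit), "ggplot")
  res <- half_life(fit, 0.001, unit = "min")
  expect_named(tidy(res),
               c("design", "j", "k", "k_minus_j", "half_life", "unit"))
})
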