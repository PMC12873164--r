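test_that("loss and change statistics satisfy their defining identities", {
  # loss(y, y(1-f)) = 100 f and change(y, y(1+g)) = 100 g over a sweep
  for (f in seq(0, 0.6, by = 0.05)) {
    expect_equal(yield_loss_per_degC(4, 4 * (1 - f)), 100 * f, tolerance = 1e-12)
  }
  for (g in seq(-0.3, 0.5, by = 0.05)) {
    expect_equal(yield_change_per_co2(4, 4 * (1 + g)), 100 * g, tolerance = 1e-12)
  }
  expect_equal(yield_loss_per_degC(4.00, 3.82), 4.5)
  expect_equal(yield_loss_per_degC(4.00, 3.76), 6.0)
  expect_equal(yield_change_per_co2(4.0, 4.3), 7.5)
  expect_equal(yield_loss_per_degC(3.1, 3.1), 0)
  expect_lt(yield_change_per_co2(4.0, 3.9), 0)
  expect_error(yield_loss_per_degC(0, 1), "ambient")
  expect_error(yield_change_per_co2(-1, 1), "base")
})

test_that("multi-increment losses average to the per-degree rate", {
  # noise-free surrogate: yields at +1..+3 C all imply the configured rate
  m <- surrogate_yield_model(baseline_yield = 4, temp_loss_rate = 0.05)
  y <- wheatclim:::surrogate_mean_yield(m, 0:3, 350)
  expect_equal(yield_loss_per_degC(y[1], y[2:4], delta_t = 1:3), 5)
  # per-100ppm scaling
  expect_equal(yield_change_per_co2(4, 4.2, co2_base = 350, co2_elev = 550),
               2.5)
})

test_that("the noise-free grid reproduces the surrogate exactly", {
  m <- surrogate_preset("islamabad")  # noise 0, 4.5 %/C
  g <- run_grid(m, deltas = 0:3, co2_levels = c(350, 450, 550), replicates = 1)
  base_cell <- g$cells$yield[g$cells$delta_t == 0 & g$cells$co2 == 350]
  expect_equal(base_cell, 4.0)
  st <- grid_stats(g)
  expect_equal(st$yield_loss_pct_per_degC, 4.5, tolerance = 1e-10)
  # monotone: non-increasing in delta-T, non-decreasing in CO2
  s <- g$summary[order(g$summary$delta_t, g$summary$co2), ]
  for (c0 in c(350, 450, 550)) {
    expect_true(all(diff(s$mean[s$co2 == c0]) <= 0))
  }
  for (d0 in 0:3) {
    expect_true(all(diff(s$mean[s$delta_t == d0]) >= 0))
  }
  chak <- run_grid(surrogate_preset("chakwal"), deltas = 0:1,
                   co2_levels = 350, replicates = 1)
  expect_equal(grid_stats(chak)$yield_loss_pct_per_degC, 6, tolerance = 1e-10)
})

test_that("grids are seed-reproducible and recover the loss rate under noise", {
  m <- surrogate_yield_model(baseline_yield = 4, temp_loss_rate = 0.045,
                             noise_sd = 0.3)
  g1 <- run_grid(m, deltas = 0:1, co2_levels = 350, replicates = 500, seed = 11)
  g2 <- run_grid(m, deltas = 0:1, co2_levels = 350, replicates = 500, seed = 11)
  expect_identical(g1$cells, g2$cells)
  est <- grid_stats(g1)$yield_loss_pct_per_degC
  # Monte-Carlo s.e. of the loss estimate: two cell means of 500 draws
  se_cell <- 0.3 / sqrt(500)
  se_loss <- 100 * sqrt(2) * se_cell / 4
  expect_lt(abs(est - 4.5), 3 * se_loss)
})

test_that("CO2 benefit cannot offset strong warming in the surrogate", {
  m <- surrogate_preset("islamabad")
  g <- run_grid(m, deltas = c(0, 8), co2_levels = c(350, 800), replicates = 1)
  y_best_co2 <- g$summary$mean[g$summary$delta_t == 8 & g$summary$co2 == 800]
  y_ambient <- g$summary$mean[g$summary$delta_t == 0 & g$summary$co2 == 350]
  # 4.5 %/C x 8 C loss exceeds the log-CO2 gain at 800 ppm
  expect_lt(y_best_co2, y_ambient)
})

test_that("apply_delta_t shifts temperatures and nothing else", {
  ws <- random_series(40, seed = 5)
  same <- apply_delta_t(ws, 0)
  expect_identical(weather_data(same), weather_data(ws))
  up <- apply_delta_t(ws, 1.5)
  expect_equal(daily_tmean(up), daily_tmean(ws) + 1.5)
  expect_identical(weather_data(up)$rain, weather_data(ws)$rain)
  expect_error(apply_delta_t(ws, NA), "finite")
})

test_that("surrogate configuration is validated", {
  expect_error(surrogate_yield_model(baseline_yield = 0), "> 0")
  expect_error(surrogate_yield_model(temp_loss_rate = 1), "\\[0, 1\\)")
  expect_error(surrogate_yield_model(noise_sd = -1), ">= 0")
  expect_error(run_grid(surrogate_preset("islamabad"), replicates = 0), ">= 1")
  expect_error(run_grid(surrogate_preset("islamabad"), deltas = numeric(0)),
               "malformed")
})
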