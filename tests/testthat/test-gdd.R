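# Independent brute-force accumulation used as the oracle: a plain loop
# re-implementing the thermal-time rules day by day, sharing no code with
# season_gdd().
brute_force_gdd <- function(df, sowing, phases, threshold = 35) {
  total <- 0; n_ceil <- 0L; n_hot <- 0L
  for (i in seq_len(nrow(df))) {
    das <- as.integer(df$date[i] - as.Date(sowing)) + 1L
    ph <- phases[[max(which(vapply(phases, `[[`, numeric(1), "start") <= das))]]
    tmean <- (df$tmax[i] + df$tmin[i]) / 2
    g <- min(max(tmean, ph$base), ph$opt) - ph$base
    if (df$tmax[i] > ph$ceil) { g <- 0; n_ceil <- n_ceil + 1L }
    total <- total + g
    if (df$tmax[i] > threshold) n_hot <- n_hot + 1L
  }
  list(total = total, n_ceil = n_ceil, n_hot = n_hot)
}

test_that("daily_gdd follows the clamped mean / ceiling-zero rules", {
  veg <- wheat_cardinals("vegetative")
  expect_equal(daily_gdd(20, 10, veg), 11)                 # (20+10)/2 - 4
  expect_equal(daily_gdd(8, 0, veg), 0)                    # Tmean at base
  expect_equal(daily_gdd(30, 20, veg), 18)                 # clamped at optimum
  expect_equal(daily_gdd(2, -6, veg), 0)                   # below base floors at 0
  gf <- wheat_cardinals("grainfill_to_maturity")
  expect_equal(daily_gdd(36, 30, gf), 0)                   # Tmax above ceiling
  expect_error(daily_gdd(5, 10, veg), "tmax < tmin")
  expect_error(cardinal_temps(10, 5, 30), "t_base < t_opt < t_ceil")
})

test_that("the trapezoidal mode declines linearly above the optimum", {
  veg <- cardinal_temps(4, 22, 32.7)
  # below the optimum the two modes agree
  expect_equal(daily_gdd(20, 10, veg, method = "trapezoid"),
               daily_gdd(20, 10, veg))
  # at Tmean halfway between optimum and ceiling the response is halved
  tmean <- (22 + 32.7) / 2
  expect_equal(daily_gdd(tmean + 2, tmean - 2, veg, method = "trapezoid"),
               (22 - 4) / 2)
  # at or beyond the ceiling it reaches zero
  expect_equal(daily_gdd(34, 31.4, veg, method = "trapezoid"), 0)
})

test_that("season_gdd sums constant series and phase switches by hand", {
  veg_only <- phase_schedule(tibble::tibble(
    label = "vegetative", start_day = 1L,
    cardinals = list(wheat_cardinals("vegetative"))))
  ws <- const_series(n = 100, tmax = 20, tmin = 10)
  sow <- weather_data(ws)$date[1]
  res <- season_gdd(ws, sow, veg_only, sow + 99)
  expect_equal(res$total_gdd, 1100)
  expect_equal(res$daily$cum_gdd, cumsum(rep(11, 100)))
  expect_identical(res$n_ceiling_days, 0L)

  # 10 vegetative days then 10 grain-fill days at the same temperatures:
  # 10 x 11 + 10 x (15 - 9.2)
  two <- phase_schedule(tibble::tibble(
    label = c("vegetative", "grainfill_to_maturity"),
    start_day = c(1L, 11L),
    cardinals = list(wheat_cardinals("vegetative"),
                     wheat_cardinals("grainfill_to_maturity"))))
  ws20 <- const_series(n = 20, tmax = 20, tmin = 10)
  res2 <- season_gdd(ws20, weather_data(ws20)$date[1], two,
                     weather_data(ws20)$date[20])
  expect_equal(res2$total_gdd, 10 * 11 + 10 * 5.8)

  # every day above its ceiling accumulates nothing
  hot <- const_series(n = 15, tmax = 40, tmin = 25)
  res3 <- season_gdd(hot, weather_data(hot)$date[1], veg_only,
                     weather_data(hot)$date[15])
  expect_equal(res3$total_gdd, 0)
  expect_identical(res3$n_ceiling_days, 15L)
  expect_identical(res3$n_days_above_threshold, 15L)
})

test_that("season_gdd equals the brute-force oracle on 100 random series", {
  sched <- wheat_schedule(12L, flowering_duration = 8L)
  phases <- list(list(start = 1, base = 4, opt = 22, ceil = 32.7),
                 list(start = 13, base = 9.5, opt = 21, ceil = 31),
                 list(start = 21, base = 9.2, opt = 20.7, ceil = 35.4))
  for (seed in 1:100) {
    ws <- random_series(30, seed = seed)
    df <- weather_data(ws)
    res <- season_gdd(ws, df$date[1], sched, df$date[30])
    oracle <- brute_force_gdd(df, df$date[1], phases)
    expect_equal(res$total_gdd, oracle$total, tolerance = 1e-9)
    expect_identical(res$n_ceiling_days, oracle$n_ceil)
    expect_identical(res$n_days_above_threshold, oracle$n_hot)
  }
})

test_that("gdd results respect monotonicity and the phase bound", {
  sched <- wheat_schedule(12L)
  for (seed in 1:20) {
    ws <- random_series(30, seed = seed)
    df <- weather_data(ws)
    res <- season_gdd(ws, df$date[1], sched, df$date[30])
    expect_true(all(diff(res$daily$cum_gdd) >= 0))
    expect_true(all(res$daily$gdd >= 0))
    expect_lte(res$total_gdd, 30 * (22 - 4))  # loosest phase span
    # warming by +1 C never decreases the total when no ceiling is crossed
    if (all(df$tmax + 1 <= 31)) {
      warmer <- apply_delta_t(ws, 1)
      res_w <- season_gdd(warmer, df$date[1], sched, df$date[30])
      expect_gte(res_w$total_gdd, res$total_gdd)
    }
  }
})

test_that("days_to_reach inverts cumulative thermal time", {
  veg_only <- phase_schedule(tibble::tibble(
    label = "vegetative", start_day = 1L,
    cardinals = list(wheat_cardinals("vegetative"))))
  ws <- const_series(n = 50, tmax = 20, tmin = 10)  # 11 degree-days per day
  sow <- weather_data(ws)$date[1]
  expect_identical(as.integer(days_to_reach(ws, sow, 110, veg_only)), 10L)
  expect_identical(as.integer(days_to_reach(ws, sow, 110.5, veg_only)), 11L)
  expect_identical(as.integer(days_to_reach(ws, sow, 5, veg_only)), 1L)
  miss <- days_to_reach(ws, sow, 1e5, veg_only)
  expect_true(is.na(miss))
  expect_false(attr(miss, "attained"))
  expect_error(days_to_reach(ws, sow, -5, veg_only), "> 0")
})

test_that("warmer series reach a thermal target no later", {
  veg_only <- phase_schedule(tibble::tibble(
    label = "vegetative", start_day = 1L,
    cardinals = list(wheat_cardinals("vegetative"))))
  ws <- harmonic_series(2000, 2001, mean_t = 15, amplitude = 8)
  sow <- as.Date("2000-10-15")
  base_day <- days_to_reach(ws, sow, 600, veg_only, end = as.Date("2001-04-30"))
  warm_day <- days_to_reach(apply_delta_t(ws, 2), sow, 600, veg_only,
                            end = as.Date("2001-04-30"))
  expect_lte(as.integer(warm_day), as.integer(base_day))
})
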