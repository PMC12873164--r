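test_that("anthesis dates reproduce the published sowing-table arithmetic", {
  # all five 100-day (Chakwal) rows under the inclusive convention
  sow <- list(c(10, 15), c(10, 25), c(11, 4), c(11, 14), c(11, 24))
  printed <- c("22-Jan", "01-Feb", "11-Feb", "21-Feb", "03-Mar")
  for (i in seq_along(sow)) {
    sc <- sowing_scenario(paste0("SD", i), sow[[i]][1], sow[[i]][2], 100)
    expect_identical(format(anthesis_date(sc), "%d-%b"), printed[i])
  }
  # the 105-day first row: 15 Oct -> 27 Jan
  sc105 <- sowing_scenario("SD1", 10, 15, 105)
  expect_identical(format(anthesis_date(sc105), "%d-%b"), "27-Jan")
  expect_error(sowing_scenario("x", 10, 15, 0), "dta_days")
})

test_that("flowering_window_temp averages the window across years", {
  ws <- const_series(start = "2018-06-01", n = 3 * 365, tmax = 17, tmin = 7)
  expect_equal(flowering_window_temp(ws, as.Date("2019-01-22"), 10), 12)
  # +1 C everywhere shifts the answer by exactly 1
  expect_equal(flowering_window_temp(apply_delta_t(ws, 1), as.Date("2019-01-22"), 10),
               13)
  # on a spring warm-up, later windows are strictly warmer
  h <- harmonic_series(2000, 2004)
  t_jan <- flowering_window_temp(h, as.Date("2001-01-22"), 10)
  t_feb <- flowering_window_temp(h, as.Date("2001-02-11"), 10)
  t_mar <- flowering_window_temp(h, as.Date("2001-03-03"), 10)
  expect_lt(t_jan, t_feb)
  expect_lt(t_feb, t_mar)
  expect_error(flowering_window_temp(const_series(n = 5), as.Date("2021-06-01"), 10),
               "never")
})

test_that("relative_rise uses the later temperature as denominator", {
  expect_equal(relative_rise(11.06, 16.61), 33.41, tolerance = 0.01 / 33.41)
  # printed as 35.67; exact arithmetic gives 35.68
  expect_equal(relative_rise(10.24, 15.92), 35.68, tolerance = 0.02 / 35.68)
  expect_equal(relative_rise(12, 12), 0)
  expect_gt(relative_rise(10, 11), 0)
  expect_lt(relative_rise(11, 10), 0)
  expect_error(relative_rise(10, 0), "denominator")
})

test_that("scenario_table rows are ordered, monotone and carry supplied losses", {
  h <- harmonic_series(2000, 2010)
  losses <- c(0, 0, 0.25, 10, 25)
  tab <- scenario_table(h, standard_scenarios("chakwal"),
                        yield_losses = losses, reference_year = 2001)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$label, paste0("SD", 1:5))
  expect_true(all(diff(tab$window_tmean) > 0))   # spring warm-up
  expect_equal(tab$relative_rise_pct[1], 0)
  expect_true(all(diff(tab$relative_rise_pct) > 0))
  expect_identical(tab$yield_loss_pct, losses)

  one <- scenario_table(h, standard_scenarios("chakwal")[1])
  expect_equal(one$relative_rise_pct, 0)

  dup <- standard_scenarios("chakwal")[c(1, 1)]
  expect_error(scenario_table(h, dup), "duplicate")
  expect_error(scenario_table(h, standard_scenarios("chakwal"), yield_losses = 1:3),
               "align")
})

test_that("stage_rainfall partitions season totals conservatively", {
  # uniform 1 mm/day: vegetative 100 days, reproductive 98 (non-leap season)
  dates <- seq(as.Date("2000-06-01"), as.Date("2003-07-31"), by = "day")
  ws <- weather_series(data.frame(date = dates, tmax = 20, tmin = 10, rain = 1),
                       site_id = "wet", latitude = 33, longitude = 73)
  out <- stage_rainfall(ws, 100, edges = c(2001L, 2004L))
  seasons <- attr(out, "seasons")
  non_leap <- seasons[seasons$harvest_year %in% c(2001, 2003), ]
  expect_true(all(non_leap$vegetative_mm == 100))
  expect_true(all(non_leap$reproductive_mm == 98))
  expect_equal(seasons$vegetative_mm + seasons$reproductive_mm,
               seasons$season_total_mm)

  # all rain before anthesis leaves the reproductive stage dry
  d2 <- weather_data(ws)
  d2$rain <- ifelse(format(d2$date, "%m") %in% c("10", "11"), 2, 0)
  ws2 <- weather_series(d2, latitude = 33, longitude = 73)
  out2 <- stage_rainfall(ws2, 100, edges = c(2001L, 2004L))
  expect_true(all(attr(out2, "seasons")$reproductive_mm == 0))

  # decadal aggregation: mean vs sum differ by the season count
  sum_out <- stage_rainfall(ws, 100, edges = c(2001L, 2004L), aggregate = "sum")
  expect_equal(sum_out$vegetative_mm, out$vegetative_mm * out$n_seasons)
  expect_error(stage_rainfall(const_series(n = 10), 100), "complete season")
})

test_that("econ_value reproduces the maund and revenue arithmetic", {
  e <- econ_value(2.4648, price_pkr_per_40kg = 3100, pkr_per_usd = 278.5)
  expect_equal(e$yield_kg, 2464.8)
  expect_equal(e$maunds, 61.62)
  expect_equal(e$revenue_pkr, 61.62 * 3100)   # 191,022 PKR
  expect_equal(e$revenue_usd, 191022 / 278.5)
  zero <- econ_value(0, pkr_per_usd = 280)
  expect_equal(zero$revenue_pkr, 0)
  expect_equal(zero$revenue_usd, 0)
  expect_true(is.na(econ_value(1)$revenue_usd))
  expect_error(econ_value(2, pkr_per_usd = -1), "exchange rate")
  expect_error(econ_value(-2), "negative")
})
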