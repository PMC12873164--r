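# Small deterministic weather fixtures built in code.

const_series <- function(start = "2020-01-01", n = 30, tmax = 20, tmin = 10,
                         rain = 0, site_id = "fix", lat = 33.0, lon = 73.0) {
  start <- as.Date(start)
  weather_series(
    data.frame(date = start + seq_len(n) - 1L,
               tmax = rep_len(tmax, n), tmin = rep_len(tmin, n),
               rain = rep_len(rain, n)),
    site_id = site_id, latitude = lat, longitude = lon)
}

# Multi-year series with a smooth seasonal cycle (coldest in mid-January)
# and no noise; handy for scenario-window monotonicity checks.
harmonic_series <- function(first_year = 2000, last_year = 2005,
                            mean_t = 20, amplitude = 10, range_c = 10,
                            rain = 0) {
  dates <- seq(as.Date(sprintf("%d-01-01", first_year)),
               as.Date(sprintf("%d-12-31", last_year)), by = "day")
  doy <- as.integer(format(dates, "%j"))
  tmean <- mean_t - amplitude * cos(2 * pi * (doy - 10) / 365.25)
  weather_series(
    data.frame(date = dates, tmax = tmean + range_c / 2,
               tmin = tmean - range_c / 2, rain = rep_len(rain, length(dates))),
    site_id = "harmonic", latitude = 33.0, longitude = 73.0)
}

random_series <- function(n = 30, seed = 1, start = "2020-01-01") {
  withr::with_seed(seed, {
    tmin <- runif(n, -2, 25)
    rng <- runif(n, 1, 15)
    weather_series(
      data.frame(date = as.Date(start) + seq_len(n) - 1L,
                 tmax = tmin + rng, tmin = tmin,
                 rain = rpois(n, 2) * runif(n, 0, 5)),
      site_id = "rand", latitude = 33.0, longitude = 73.0)
  })
}

tiny_gen_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(annual_mean_temp = 22, seasonal_amplitude = 10,
         warming_trend = 0, start_year = 2019L, end_year = 2020L,
         seed = as.integer(seed), latitude = 33.0, longitude = 73.0),
    list(...))
  do.call(climate_gen_config, args)
}
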