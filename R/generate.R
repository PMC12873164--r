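#' Configuration for the stochastic daily weather generator
#'
#' The generator layers four components the downstream analysis assumes:
#' a linear warming trend, a single-harmonic seasonal cycle, AR(1) daily
#' temperature noise, and two-state Markov-chain rainfall occurrence with
#' gamma-distributed wet-day amounts. Rainfall is generated on an
#' independent random substream so that toggling it never perturbs the
#' temperature draws.
#'
#' @param annual_mean_temp long-run annual mean temperature at the start of
#'   the series, degrees C.
#' @param seasonal_amplitude half peak-to-trough amplitude of the seasonal
#'   harmonic, degrees C.
#' @param coldest_doy day-of-year of the seasonal minimum (default 10,
#'   i.e. around 10 January).
#' @param warming_trend linear trend, degrees C per decade, applied to daily
#'   mean temperature as `warming_trend * years_since_start / 10`.
#' @param diurnal_range_mean,diurnal_range_sd mean and SD of the daily
#'   Tmax - Tmin range, degrees C; sampled ranges are floored at 0.1 so the
#'   range stays positive.
#' @param ar1_coeff lag-1 autocorrelation of the daily temperature residual,
#'   in (-1, 1).
#' @param residual_sd stationary SD of the daily temperature residual,
#'   degrees C.
#' @param p_wet_given_dry,p_wet_given_wet Markov transition probabilities of
#'   a wet day following a dry / wet day.
#' @param rain_gamma_shape,rain_gamma_scale gamma parameters of wet-day
#'   rainfall amounts (scale in mm).
#' @param start_year,end_year first and last harvest year; the generated
#'   series spans 1 January of `start_year - 1` through 31 December of
#'   `end_year`, so every season window ending in `start_year..end_year` is
#'   fully covered.
#' @param seed master integer seed; all randomness derives from it.
#' @param site_id,latitude,longitude metadata attached to the generated
#'   series.
#' @return An object of class `climate_gen_config` (a validated list).
#' @seealso [generate_series()], [site_preset()]
#' @export
climate_gen_config <- function(annual_mean_temp,
                               seasonal_amplitude,
                               coldest_doy = 10L,
                               warming_trend = 0,
                               diurnal_range_mean = 12,
                               diurnal_range_sd = 3,
                               ar1_coeff = 0.7,
                               residual_sd = 2,
                               p_wet_given_dry = 0.1,
                               p_wet_given_wet = 0.4,
                               rain_gamma_shape = 0.5,
                               rain_gamma_scale = 20,
                               start_year = 1980L,
                               end_year = 2020L,
                               seed = 1L,
                               site_id = "synthetic",
                               latitude = NA_real_,
                               longitude = NA_real_) {
  cfg <- list(annual_mean_temp = as.numeric(annual_mean_temp),
              seasonal_amplitude = as.numeric(seasonal_amplitude),
              coldest_doy = as.integer(coldest_doy),
              warming_trend = as.numeric(warming_trend),
              diurnal_range_mean = as.numeric(diurnal_range_mean),
              diurnal_range_sd = as.numeric(diurnal_range_sd),
              ar1_coeff = as.numeric(ar1_coeff),
              residual_sd = as.numeric(residual_sd),
              p_wet_given_dry = as.numeric(p_wet_given_dry),
              p_wet_given_wet = as.numeric(p_wet_given_wet),
              rain_gamma_shape = as.numeric(rain_gamma_shape),
              rain_gamma_scale = as.numeric(rain_gamma_scale),
              start_year = as.integer(start_year),
              end_year = as.integer(end_year),
              seed = as.integer(seed),
              site_id = as.character(site_id),
              latitude = as.numeric(latitude),
              longitude = as.numeric(longitude))
  validate_climate_config(cfg)
  structure(cfg, class = "climate_gen_config")
}

validate_climate_config <- function(cfg) {
  if (cfg$diurnal_range_sd <= 0 || cfg$residual_sd <= 0) {
    stop("climate_gen_config(): standard deviations must be > 0", call. = FALSE)
  }
  if (abs(cfg$ar1_coeff) >= 1) {
    stop("climate_gen_config(): |ar1_coeff| must be < 1", call. = FALSE)
  }
  probs <- c(cfg$p_wet_given_dry, cfg$p_wet_given_wet)
  if (any(probs < 0 | probs > 1)) {
    stop("climate_gen_config(): transition probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$rain_gamma_shape <= 0 || cfg$rain_gamma_scale <= 0) {
    stop("climate_gen_config(): gamma parameters must be > 0", call. = FALSE)
  }
  if (cfg$end_year < cfg$start_year) {
    stop("climate_gen_config(): end_year must be >= start_year", call. = FALSE)
  }
  if (cfg$coldest_doy < 1L || cfg$coldest_doy > 366L) {
    stop("climate_gen_config(): coldest_doy must lie in 1..366", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.climate_gen_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<climate_gen_config> '%s' %d-%d (seed %d)\n",
    "  Tmean %.1f C + %.2f C/decade, amplitude %.1f C (coldest doy %d)\n",
    "  AR(1) %.2f, residual sd %.2f C, diurnal range %.1f +/- %.1f C\n",
    "  rain: P(w|d) %.2f, P(w|w) %.2f, gamma(%.2f, scale %.1f mm)\n"),
    x$site_id, x$start_year, x$end_year, x$seed,
    x$annual_mean_temp, x$warming_trend, x$seasonal_amplitude, x$coldest_doy,
    x$ar1_coeff, x$residual_sd, x$diurnal_range_mean, x$diurnal_range_sd,
    x$p_wet_given_dry, x$p_wet_given_wet, x$rain_gamma_shape,
    x$rain_gamma_scale))
  invisible(x)
}

# Deterministic (noise-free) daily mean temperature for a date vector:
# annual mean + warming trend + seasonal harmonic with minimum at coldest_doy.
deterministic_tmean <- function(cfg, dates) {
  first <- as.Date(sprintf("%04d-01-01", cfg$start_year - 1L))
  elapsed_years <- as.numeric(dates - first) / 365.25
  doy <- as.integer(format(dates, "%j"))
  cfg$annual_mean_temp +
    cfg$warming_trend * elapsed_years / 10 -
    cfg$seasonal_amplitude * cos(2 * pi * (doy - cfg$coldest_doy) / 365.25)
}

#' Generate a multi-decadal daily weather series
#'
#' Daily mean temperature is the sum of the configured annual mean, the
#' linear warming trend, the seasonal harmonic and a stationary AR(1)
#' residual; Tmax/Tmin are split around it by a sampled diurnal range.
#' Rainfall occurrence follows a two-state Markov chain and wet-day amounts
#' a gamma distribution. The whole series is reproducible from
#' `config$seed`.
#'
#' @param config a [climate_gen_config()].
#' @return A [weather_series()] spanning 1 January of `start_year - 1`
#'   through 31 December of `end_year`.
#' @examples
#' cfg <- climate_gen_config(annual_mean_temp = 22, seasonal_amplitude = 10,
#'                           start_year = 2019, end_year = 2020, seed = 42)
#' ws <- generate_series(cfg)
#' range(weather_data(ws)$date)
#' @export
generate_series <- function(config) {
  if (!inherits(config, "climate_gen_config")) {
    config <- do.call(climate_gen_config, as.list(config))
  }
  validate_climate_config(config)
  dates <- seq(as.Date(sprintf("%04d-01-01", config$start_year - 1L)),
               as.Date(sprintf("%04d-12-31", config$end_year)),
               by = "day")
  n <- length(dates)

  # one master seed spawns independent substreams for temperature and rain
  seeds <- withr::with_seed(config$seed, sample.int(2147483646L, 2L))

  tmean_det <- deterministic_tmean(config, dates)
  temp <- withr::with_seed(seeds[1], {
    innov_sd <- config$residual_sd * sqrt(1 - config$ar1_coeff^2)
    innov <- stats::rnorm(n, 0, innov_sd)
    resid <- as.numeric(stats::filter(
      innov, config$ar1_coeff, method = "recursive",
      init = stats::rnorm(1, 0, config$residual_sd)))
    rng <- pmax(stats::rnorm(n, config$diurnal_range_mean,
                             config$diurnal_range_sd), 0.1)
    tmean <- tmean_det + resid
    list(tmax = tmean + rng / 2, tmin = tmean - rng / 2)
  })

  rain <- withr::with_seed(seeds[2], {
    p_stat <- config$p_wet_given_dry /
      (1 + config$p_wet_given_dry - config$p_wet_given_wet)
    u <- stats::runif(n)
    wet <- logical(n)
    wet[1] <- u[1] < p_stat
    for (i in seq_len(n)[-1]) {
      p <- if (wet[i - 1L]) config$p_wet_given_wet else config$p_wet_given_dry
      wet[i] <- u[i] < p
    }
    amounts <- numeric(n)
    amounts[wet] <- stats::rgamma(sum(wet), shape = config$rain_gamma_shape,
                                  scale = config$rain_gamma_scale)
    amounts
  })

  weather_series(
    data.frame(date = dates, tmax = temp$tmax, tmin = temp$tmin, rain = rain),
    site_id = config$site_id, latitude = config$latitude,
    longitude = config$longitude)
}

#' Seasonal mean temperatures of a multi-year series
#'
#' One row per fully covered season window: harvest year, seasonal mean of
#' daily mean temperature, and seasonal rainfall total.
#'
#' @param series a [weather_series()].
#' @param window a [season_window()].
#' @return A tibble with columns `harvest_year`, `season_tmean`,
#'   `season_rain`, `n_days`.
#' @export
seasonal_summary <- function(series, window = season_window()) {
  yrs <- covered_harvest_years(series, window)
  if (!length(yrs)) {
    stop("seasonal_summary(): no fully covered season in the series", call. = FALSE)
  }
  rows <- lapply(yrs, function(y) {
    s <- extract_season(series, window, y)
    d <- weather_data(s)
    tibble::tibble(harvest_year = y,
                   season_tmean = mean((d$tmax + d$tmin) / 2),
                   season_rain = sum(d$rain),
                   n_days = nrow(d))
  })
  dplyr::bind_rows(rows)
}
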