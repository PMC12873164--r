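#' Daily weather series for one site
#'
#' The central data container: an ordered table of daily records (date,
#' maximum temperature, minimum temperature, rainfall) plus site metadata.
#' Validity rules: dates strictly increasing, `tmax >= tmin` on every day,
#' `rain >= 0`. Gaps in the date sequence are rejected in strict mode and
#' flagged (`gaps` attribute) in gap-tolerant mode.
#'
#' @param data a data frame with columns `date` (`Date`), `tmax`, `tmin`
#'   (degrees C) and `rain` (mm).
#' @param site_id character site identifier.
#' @param latitude,longitude site coordinates in decimal degrees (may be `NA`
#'   for in-memory work; required when writing station-format files).
#' @param strict logical; if `TRUE` (default) any invalid row or date gap is
#'   an error, otherwise invalid rows are dropped and gaps recorded.
#' @return An object of class `weather_series`: a list with elements
#'   `site_id`, `latitude`, `longitude`, `data` (a tibble) and `gaps`.
#' @examples
#' ws <- weather_series(
#'   data.frame(date = as.Date("2020-01-01") + 0:2,
#'              tmax = c(18, 19, 17), tmin = c(5, 6, 4), rain = c(0, 2.5, 0)),
#'   site_id = "demo", latitude = 33.67, longitude = 73.13)
#' n_days(ws)
#' @export
weather_series <- function(data, site_id = "site", latitude = NA_real_,
                           longitude = NA_real_, strict = TRUE) {
  req <- c("date", "tmax", "tmin", "rain")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("weather_series(): missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data[req])
  data$date <- as.Date(data$date)
  data$tmax <- as.numeric(data$tmax)
  data$tmin <- as.numeric(data$tmin)
  data$rain <- as.numeric(data$rain)
  if (nrow(data) == 0L) stop("weather_series(): empty series", call. = FALSE)
  if (anyNA(data$date)) stop("weather_series(): unparseable or NA dates", call. = FALSE)
  if (anyDuplicated(data$date)) {
    stop("weather_series(): duplicate dates", call. = FALSE)
  }
  data <- data[order(data$date), ]

  bad <- which(!is.na(data$tmax) & !is.na(data$tmin) & data$tmax < data$tmin)
  bad <- union(bad, which(!is.na(data$rain) & data$rain < 0))
  bad <- union(bad, which(is.na(data$tmax) | is.na(data$tmin) | is.na(data$rain)))
  bad <- sort(bad)
  if (length(bad)) {
    if (strict) {
      stop("weather_series(): invalid record(s) at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           " (tmax < tmin, negative rain, or NA)", call. = FALSE)
    }
    data <- data[-bad, ]
    if (nrow(data) == 0L) stop("weather_series(): no valid records left", call. = FALSE)
  }

  gaps <- find_date_gaps(data$date)
  if (strict && nrow(gaps)) {
    stop("weather_series(): date gaps present (first gap after ",
         format(gaps$after[1]), "); use strict = FALSE to flag instead",
         call. = FALSE)
  }

  structure(
    list(site_id = as.character(site_id),
         latitude = as.numeric(latitude),
         longitude = as.numeric(longitude),
         data = data,
         gaps = gaps),
    class = "weather_series"
  )
}

find_date_gaps <- function(dates) {
  d <- diff(as.integer(dates))
  idx <- which(d > 1L)
  tibble::tibble(after = dates[idx], missing_days = d[idx] - 1L)
}

#' @export
print.weather_series <- function(x, ...) {
  rng <- range(x$data$date)
  cat(sprintf("<weather_series> site '%s' (%.2f, %.2f): %d days, %s .. %s\n",
              x$site_id, x$latitude, x$longitude, nrow(x$data),
              format(rng[1]), format(rng[2])))
  if (nrow(x$gaps)) cat(sprintf("  %d flagged date gap(s)\n", nrow(x$gaps)))
  invisible(x)
}

#' @rdname weather_series
#' @param series a `weather_series`.
#' @export
weather_data <- function(series) {
  stopifnot(inherits(series, "weather_series"))
  series$data
}

#' @rdname weather_series
#' @export
n_days <- function(series) nrow(weather_data(series))

#' Daily mean temperature of a series, (tmax + tmin) / 2
#' @param series a `weather_series`.
#' @return Numeric vector aligned with the series rows.
#' @export
daily_tmean <- function(series) {
  d <- weather_data(series)
  (d$tmax + d$tmin) / 2
}

#' Extract one growing season from a multi-year series
#'
#' Returns the sub-series covering the season window ending in
#' `harvest_year` (for the default 15 Oct - 30 Apr window: 15 October of
#' `harvest_year - 1` through 30 April of `harvest_year`, inclusive). The
#' window must be fully covered, otherwise the missing span is reported.
#'
#' @param series a [weather_series()].
#' @param window a [season_window()]; defaults to the rabi wheat season.
#' @param harvest_year integer year in which the season ends.
#' @return A `weather_series` restricted to the window; its length equals
#'   `day_count_inclusive(start, end)` (198 for the default window over a
#'   non-leap February, 199 otherwise).
#' @export
extract_season <- function(series, window = season_window(), harvest_year) {
  stopifnot(inherits(series, "weather_series"))
  ends <- season_dates(window, harvest_year)
  d <- series$data
  keep <- d$date >= ends$start & d$date <= ends$end
  sub <- d[keep, ]
  expected <- day_count_inclusive(ends$start, ends$end)
  if (nrow(sub) != expected) {
    have <- sub$date
    want <- seq(ends$start, ends$end, by = "day")
    miss <- want[!want %in% have]
    stop(sprintf(
      "extract_season(): window %s..%s not fully covered; %d day(s) missing (%s%s)",
      format(ends$start), format(ends$end), length(miss),
      paste(format(utils::head(miss, 3L)), collapse = ", "),
      if (length(miss) > 3L) ", ..." else ""), call. = FALSE)
  }
  out <- series
  out$data <- sub
  out$gaps <- find_date_gaps(sub$date)
  out
}

#' Harvest years whose season window is fully covered by a series
#' @inheritParams extract_season
#' @return Integer vector of harvest years.
#' @export
covered_harvest_years <- function(series, window = season_window()) {
  d <- weather_data(series)
  yrs <- sort(unique(as.integer(format(d$date, "%Y"))))
  ok <- vapply(yrs, function(y) {
    ends <- tryCatch(season_dates(window, y), error = function(e) NULL)
    if (is.null(ends)) return(FALSE)
    expected <- day_count_inclusive(ends$start, ends$end)
    sum(d$date >= ends$start & d$date <= ends$end) == expected
  }, logical(1))
  yrs[ok]
}
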