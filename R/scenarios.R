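#' A sowing-date scenario
#'
#' One row of a sowing-date experiment: a label (SD1..SD5 in the standard
#' set), a (month, day) sowing date, the fixed long-term days to anthesis
#' for the site, and the flowering-window length.
#'
#' @param label scenario label.
#' @param sowing_month,sowing_day calendar sowing date.
#' @param dta_days fixed days to anthesis (inclusive convention; 105 for
#'   Islamabad, 100 for Chakwal in the standard sets).
#' @param flowering_duration flowering-window length in days (default 10).
#' @return An object of class `sowing_scenario`.
#' @seealso [standard_scenarios()]
#' @export
sowing_scenario <- function(label, sowing_month, sowing_day, dta_days,
                            flowering_duration = 10L) {
  dta_days <- as.integer(dta_days)
  flowering_duration <- as.integer(flowering_duration)
  if (dta_days < 1L) stop("sowing_scenario(): dta_days must be >= 1", call. = FALSE)
  if (flowering_duration < 1L) {
    stop("sowing_scenario(): flowering_duration must be >= 1", call. = FALSE)
  }
  # validate month/day against a leap reference year
  if (is.na(as.Date(sprintf("2000-%02d-%02d", sowing_month, sowing_day)))) {
    stop("sowing_scenario(): invalid sowing month/day", call. = FALSE)
  }
  structure(list(label = as.character(label),
                 sowing_month = as.integer(sowing_month),
                 sowing_day = as.integer(sowing_day),
                 dta_days = dta_days,
                 flowering_duration = flowering_duration),
            class = "sowing_scenario")
}

#' The standard five sowing-date scenarios for a site
#'
#' SD1..SD5 sow on 15 October, 25 October, 4 November, 14 November and
#' 24 November, with days to anthesis fixed at the site's long-term value
#' (105 days Islamabad, 100 days Chakwal) and a 10-day flowering window.
#'
#' @param site `"islamabad"` or `"chakwal"`, or supply `dta_days` directly.
#' @param dta_days override for the fixed days to anthesis.
#' @return A list of five [sowing_scenario()] objects.
#' @export
standard_scenarios <- function(site = c("islamabad", "chakwal"),
                               dta_days = NULL) {
  if (is.null(dta_days)) {
    site <- match.arg(site)
    dta_days <- if (site == "islamabad") 105L else 100L
  }
  dates <- list(c(10L, 15L), c(10L, 25L), c(11L, 4L), c(11L, 14L), c(11L, 24L))
  lapply(seq_along(dates), function(i) {
    sowing_scenario(paste0("SD", i), dates[[i]][1], dates[[i]][2], dta_days)
  })
}

#' Anthesis date of a sowing scenario
#'
#' Day `dta_days` counting the sowing day as day 1, placed in a non-leap
#' reference year by default (scenario tables use non-leap calendar
#' arithmetic).
#'
#' @param scenario a [sowing_scenario()].
#' @param reference_year harvest year used for the calendar (default 2021,
#'   non-leap; the sowing falls in `reference_year - 1` when sown in
#'   autumn).
#' @return A `Date`.
#' @examples
#' sc <- sowing_scenario("SD1", 10, 15, 100)
#' anthesis_date(sc) # 22 January
#' @export
anthesis_date <- function(scenario, reference_year = 2021L) {
  stopifnot(inherits(scenario, "sowing_scenario"))
  sow_year <- if (scenario$sowing_month >= 7L) reference_year - 1L else reference_year
  sowing <- as.Date(sprintf("%04d-%02d-%02d", sow_year,
                            scenario$sowing_month, scenario$sowing_day))
  add_days_inclusive(sowing, scenario$dta_days)
}

#' Long-term mean temperature of the flowering window
#'
#' The window is the `duration` days starting at the anthesis date
#' (inclusive). Its (month, day) span is applied to every year present in
#' the series; the daily mean temperatures inside each year's window are
#' averaged, then averaged across years, giving the long-term flowering
#' temperature of a scenario table.
#'
#' @param series a [weather_series()].
#' @param anthesis anthesis `Date` (its year is only used for the month-day
#'   pattern).
#' @param duration window length in days (default 10).
#' @return Long-term mean temperature, degrees C.
#' @export
flowering_window_temp <- function(series, anthesis, duration = 10L) {
  stopifnot(inherits(series, "weather_series"))
  anthesis <- as.Date(anthesis)
  duration <- as.integer(duration)
  if (duration < 1L) stop("flowering_window_temp(): duration must be >= 1",
                          call. = FALSE)
  d <- weather_data(series)
  tmean <- (d$tmax + d$tmin) / 2
  md <- format(anthesis, "%m-%d")
  years <- sort(unique(as.integer(format(d$date, "%Y"))))
  vals <- c()
  for (y in years) {
    start <- suppressWarnings(as.Date(sprintf("%04d-%s", y, md)))
    if (is.na(start)) next  # 29 Feb anthesis in a non-leap year
    win <- seq(start, by = "day", length.out = duration)
    idx <- match(win, d$date)
    if (anyNA(idx)) next
    vals <- c(vals, mean(tmean[idx]))
  }
  if (!length(vals)) {
    stop("flowering_window_temp(): window ", md, " + ", duration,
         " days never fully covered by the series", call. = FALSE)
  }
  mean(vals)
}

#' Relative rise of flowering temperature against the earliest sowing
#'
#' The percentage rise of a later sowing's flowering temperature `t_k` over
#' the earliest sowing's `t_first`, normalised by the LATER value:
#' `(t_k - t_first) / t_k * 100`. With the standard Table-4 temperatures
#' this gives 33.41 % (Islamabad, 11.06 vs 16.61 C) and 35.68 % (Chakwal,
#' 10.24 vs 15.92 C).
#'
#' @param t_first flowering temperature of the earliest sowing, degrees C.
#' @param t_k flowering temperature of the later sowing, degrees C; must be
#'   nonzero.
#' @return Percentage rise (positive iff `t_k > t_first`).
#' @export
relative_rise <- function(t_first, t_k) {
  t_first <- as.numeric(t_first); t_k <- as.numeric(t_k)
  if (any(t_k == 0)) stop("relative_rise(): zero denominator", call. = FALSE)
  (t_k - t_first) / t_k * 100
}

#' Assemble a sowing-date scenario table
#'
#' One row per scenario, in sowing order: sowing date, fixed days to
#' anthesis, anthesis date, flowering-window mean temperature from the
#' weather series, relative temperature rise versus the first scenario, and
#' a yield-loss column. Yield losses are data, not computation: supply the
#' site's crop-model losses via `yield_losses`, or leave `NULL` for `NA`.
#'
#' @param series a [weather_series()] providing the long-term climatology.
#' @param scenarios list of [sowing_scenario()] with unique labels.
#' @param yield_losses optional numeric vector (percent) aligned with
#'   `scenarios`.
#' @param reference_year passed to [anthesis_date()].
#' @return A tibble with one row per scenario.
#' @export
scenario_table <- function(series, scenarios, yield_losses = NULL,
                           reference_year = 2021L) {
  labels <- vapply(scenarios, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    stop("scenario_table(): duplicate scenario labels", call. = FALSE)
  }
  if (!is.null(yield_losses) && length(yield_losses) != length(scenarios)) {
    stop("scenario_table(): yield_losses must align with scenarios", call. = FALSE)
  }
  rows <- lapply(seq_along(scenarios), function(i) {
    sc <- scenarios[[i]]
    anth <- anthesis_date(sc, reference_year)
    tibble::tibble(
      label = sc$label,
      sowing = format(anth - (sc$dta_days - 1L), "%d-%b"),
      dta_days = sc$dta_days,
      anthesis = format(anth, "%d-%b"),
      flowering_duration = sc$flowering_duration,
      window_tmean = flowering_window_temp(series, anth, sc$flowering_duration))
  })
  out <- dplyr::bind_rows(rows)
  out$relative_rise_pct <- relative_rise(out$window_tmean[1], out$window_tmean)
  out$yield_loss_pct <- if (is.null(yield_losses)) NA_real_ else as.numeric(yield_losses)
  out
}

#' Stage-partitioned rainfall by decade
#'
#' Splits each season's rainfall at the site's fixed days-to-anthesis:
#' vegetative = sowing through anthesis day (days 1..DTA), reproductive =
#' the remainder of the season window. Per-season sums are then aggregated
#' within decades, by mean (default) or sum. The split conserves the season
#' total exactly.
#'
#' @param series a multi-season [weather_series()].
#' @param dta_days fixed days to anthesis delimiting the stages.
#' @param window a [season_window()].
#' @param edges decade edges as in [decadal_summary()].
#' @param aggregate `"mean"` or `"sum"` within decades.
#' @return A tibble with `decade`, `n_seasons`, `vegetative_mm`,
#'   `reproductive_mm`, plus a per-season tibble in attribute `"seasons"`.
#' @export
stage_rainfall <- function(series, dta_days, window = season_window(),
                           edges = c(1980L, 1990L, 2000L, 2010L, 2021L),
                           aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  dta_days <- as.integer(dta_days)
  yrs <- covered_harvest_years(series, window)
  if (!length(yrs)) stop("stage_rainfall(): no complete season in series", call. = FALSE)
  seasons <- dplyr::bind_rows(lapply(yrs, function(y) {
    s <- extract_season(series, window, y)
    d <- weather_data(s)
    das <- seq_len(nrow(d))
    veg <- sum(d$rain[das <= dta_days])
    rep <- sum(d$rain[das > dta_days])
    tibble::tibble(harvest_year = y, vegetative_mm = veg,
                   reproductive_mm = rep, season_total_mm = veg + rep)
  }))
  agg <- if (aggregate == "mean") mean else sum
  edges <- sort(as.integer(edges))
  bin <- findInterval(seasons$harvest_year, edges, rightmost.closed = TRUE)
  rows <- lapply(seq_len(length(edges) - 1L), function(k) {
    v <- seasons[bin == k & seasons$harvest_year >= edges[1] &
                   seasons$harvest_year <= edges[length(edges)], ]
    lab <- sprintf("%d-%d", edges[k],
                   if (k == length(edges) - 1L) edges[k + 1L] else edges[k + 1L] - 1L)
    tibble::tibble(decade = lab, n_seasons = nrow(v),
                   vegetative_mm = if (nrow(v)) agg(v$vegetative_mm) else NA_real_,
                   reproductive_mm = if (nrow(v)) agg(v$reproductive_mm) else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seasons") <- seasons
  attr(out, "aggregate") <- aggregate
  out
}

#' Wheat revenue arithmetic in maunds, PKR and USD
#'
#' Converts grain yield to 40-kg maunds and revenue at a fixed support
#' price: `maunds = yield_kg / 40`, `revenue_pkr = maunds * price`,
#' `revenue_usd = revenue_pkr / fx`. At the reference support price of
#' 3100 PKR per 40 kg, 2.4648 t/ha is 61.62 maunds.
#'
#' @param yield_t_ha grain yield, t/ha.
#' @param price_pkr_per_40kg support price, PKR per 40-kg maund (default
#'   3100).
#' @param pkr_per_usd exchange rate, PKR per USD; required for the USD
#'   figure and must be positive.
#' @return A one-row tibble with `yield_kg`, `maunds`, `revenue_pkr`,
#'   `revenue_usd`.
#' @export
econ_value <- function(yield_t_ha, price_pkr_per_40kg = 3100,
                       pkr_per_usd = NULL) {
  yield_t_ha <- as.numeric(yield_t_ha)
  if (any(yield_t_ha < 0)) stop("econ_value(): negative yield", call. = FALSE)
  if (price_pkr_per_40kg <= 0) stop("econ_value(): non-positive price", call. = FALSE)
  if (!is.null(pkr_per_usd) && pkr_per_usd <= 0) {
    stop("econ_value(): non-positive exchange rate", call. = FALSE)
  }
  yield_kg <- yield_t_ha * 1000
  maunds <- yield_kg / 40
  revenue_pkr <- maunds * price_pkr_per_40kg
  tibble::tibble(
    yield_kg = yield_kg,
    maunds = maunds,
    revenue_pkr = revenue_pkr,
    revenue_usd = if (is.null(pkr_per_usd)) NA_real_ else revenue_pkr / pkr_per_usd)
}
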