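#' Cardinal temperatures of a crop development phase
#'
#' The three cardinal temperatures bound the thermal response of a phase:
#' development stops below the base, proceeds fastest at the optimum, and
#' stops above the ceiling. Defaults for the three wheat phases are provided
#' by [wheat_cardinals()].
#'
#' @param t_base,t_opt,t_ceil degrees C with `t_base < t_opt < t_ceil`.
#' @return An object of class `cardinal_temps`.
#' @export
cardinal_temps <- function(t_base, t_opt, t_ceil) {
  v <- c(t_base = as.numeric(t_base), t_opt = as.numeric(t_opt),
         t_ceil = as.numeric(t_ceil))
  if (anyNA(v)) stop("cardinal_temps(): values must be finite", call. = FALSE)
  if (!(v[1] < v[2] && v[2] < v[3])) {
    stop("cardinal_temps(): require t_base < t_opt < t_ceil", call. = FALSE)
  }
  structure(as.list(v), class = "cardinal_temps")
}

#' @export
print.cardinal_temps <- function(x, ...) {
  cat(sprintf("<cardinal_temps> base %.1f / opt %.1f / ceil %.1f C\n",
              x$t_base, x$t_opt, x$t_ceil))
  invisible(x)
}

#' Cardinal-temperature sets for the three wheat phases
#'
#' The Porter-and-Gawith-style triplets used for rabi wheat: sowing to
#' anthesis 4 / 22.0 / 32.7 C, anthesis to grain filling 9.5 / 21.0 /
#' 31.0 C, grain filling to maturity 9.2 / 20.7 / 35.4 C.
#'
#' @param phase one of `"vegetative"`, `"anthesis_to_grainfill"`,
#'   `"grainfill_to_maturity"`.
#' @return A [cardinal_temps()].
#' @export
wheat_cardinals <- function(phase = c("vegetative", "anthesis_to_grainfill",
                                      "grainfill_to_maturity")) {
  phase <- match.arg(phase)
  switch(phase,
         vegetative = cardinal_temps(4, 22.0, 32.7),
         anthesis_to_grainfill = cardinal_temps(9.5, 21.0, 31.0),
         grainfill_to_maturity = cardinal_temps(9.2, 20.7, 35.4))
}

#' Phase schedule mapping days after sowing to cardinal temperatures
#'
#' @param phases a data frame (or list of lists) with columns `label`,
#'   `start_day` (day after sowing at which the phase begins, sowing day =
#'   1) and `cardinals` (a list-column of [cardinal_temps()]). Starts must
#'   be strictly increasing and the first phase must start at day 1.
#' @param heat_zero_threshold Tmax threshold (degrees C, default 35) above
#'   which a day is counted as a heat-stress day, reported separately from
#'   the per-phase ceiling rule.
#' @return An object of class `phase_schedule`.
#' @seealso [wheat_schedule()] for the standard three-phase wheat schedule.
#' @export
phase_schedule <- function(phases, heat_zero_threshold = 35) {
  if (!is.data.frame(phases)) phases <- dplyr::bind_rows(lapply(phases, tibble::as_tibble))
  stopifnot(all(c("label", "start_day", "cardinals") %in% names(phases)))
  phases$start_day <- as.integer(phases$start_day)
  if (phases$start_day[1] != 1L) {
    stop("phase_schedule(): first phase must start at day 1", call. = FALSE)
  }
  if (nrow(phases) > 1L && any(diff(phases$start_day) <= 0L)) {
    stop("phase_schedule(): phase start days must be strictly increasing",
         call. = FALSE)
  }
  ok <- vapply(phases$cardinals, inherits, logical(1), "cardinal_temps")
  if (!all(ok)) stop("phase_schedule(): cardinals must be cardinal_temps objects",
                     call. = FALSE)
  structure(list(phases = tibble::as_tibble(phases),
                 heat_zero_threshold = as.numeric(heat_zero_threshold)),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("<phase_schedule>\n")
  for (i in seq_len(nrow(x$phases))) {
    cc <- x$phases$cardinals[[i]]
    cat(sprintf("  day %3d+  %-22s %.1f/%.1f/%.1f C\n",
                x$phases$start_day[i], x$phases$label[i],
                cc$t_base, cc$t_opt, cc$t_ceil))
  }
  cat(sprintf("  heat-day threshold: Tmax > %.1f C\n", x$heat_zero_threshold))
  invisible(x)
}

#' Standard three-phase wheat schedule from anthesis and maturity days
#'
#' Vegetative phase covers days 1..DTA, the anthesis-to-grain-fill phase the
#' following `flowering_duration` days, and grain-fill-to-maturity the
#' remainder.
#'
#' @param dta days to anthesis (day after sowing, inclusive convention).
#' @param flowering_duration length of the anthesis window, days (default
#'   10).
#' @param heat_zero_threshold see [phase_schedule()].
#' @return A [phase_schedule()].
#' @export
wheat_schedule <- function(dta, flowering_duration = 10L,
                           heat_zero_threshold = 35) {
  dta <- as.integer(dta)
  if (dta < 1L) stop("wheat_schedule(): dta must be >= 1", call. = FALSE)
  phase_schedule(tibble::tibble(
    label = c("vegetative", "anthesis_to_grainfill", "grainfill_to_maturity"),
    start_day = c(1L, dta + 1L, dta + as.integer(flowering_duration) + 1L),
    cardinals = list(wheat_cardinals("vegetative"),
                     wheat_cardinals("anthesis_to_grainfill"),
                     wheat_cardinals("grainfill_to_maturity"))),
    heat_zero_threshold = heat_zero_threshold)
}

#' Daily growing degree days under cardinal temperatures
#'
#' The default (`method = "clamp"`) rule: the daily mean `(tmax + tmin) / 2`
#' is clamped to `[t_base, t_opt]` and the base subtracted, so the value
#' lies in `[0, t_opt - t_base]`; a day whose Tmax exceeds the phase ceiling
#' contributes zero (the ceiling-zero rule). The alternative
#' `method = "trapezoid"` scales thermal time down linearly between the
#' optimum and the ceiling instead of using the hard cutoff; it is an
#' optional response shape, not the default.
#'
#' @param tmax,tmin daily extremes, degrees C, `tmax >= tmin`; vectorised.
#' @param cardinals a [cardinal_temps()].
#' @param method `"clamp"` (default) or `"trapezoid"`.
#' @return Numeric GDD in degree-days, `>= 0`.
#' @examples
#' daily_gdd(20, 10, wheat_cardinals("vegetative")) # 11
#' @export
daily_gdd <- function(tmax, tmin, cardinals,
                      method = c("clamp", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(inherits(cardinals, "cardinal_temps"))
  tmax <- as.numeric(tmax); tmin <- as.numeric(tmin)
  if (anyNA(tmax) || anyNA(tmin)) stop("daily_gdd(): NA temperatures", call. = FALSE)
  if (any(tmax < tmin)) stop("daily_gdd(): tmax < tmin", call. = FALSE)
  tmean <- (tmax + tmin) / 2
  tb <- cardinals$t_base; to <- cardinals$t_opt; tc <- cardinals$t_ceil
  if (method == "clamp") {
    g <- pmin(pmax(tmean, tb), to) - tb
    g[tmax > tc] <- 0
  } else {
    # piecewise-linear response: rises (T - base)/(opt - base), then falls
    # (ceil - T)/(ceil - opt); scaled to degree-days at the optimum
    f <- ifelse(tmean <= tb | tmean >= tc, 0,
                ifelse(tmean <= to, (tmean - tb) / (to - tb),
                       (tc - tmean) / (tc - to)))
    g <- f * (to - tb)
  }
  g
}

#' Seasonal GDD accumulation under a phase schedule
#'
#' Sums [daily_gdd()] from sowing to `end`, choosing each day's cardinal
#' temperatures by its day-after-sowing phase; also counts days zeroed by
#' their phase ceiling and days with Tmax above the heat threshold.
#'
#' @param series a [weather_series()] covering `[sowing, end]`.
#' @param sowing sowing date (day 1).
#' @param schedule a [phase_schedule()].
#' @param end last accumulation date (e.g. maturity).
#' @param method passed to [daily_gdd()].
#' @return An object of class `gdd_result`: list with `daily` (tibble of
#'   date, day_after_sowing, phase, tmax, tmin, gdd, cum_gdd), `total_gdd`,
#'   `n_ceiling_days`, `n_days_above_threshold`.
#' @export
season_gdd <- function(series, sowing, schedule, end,
                       method = c("clamp", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "weather_series"),
            inherits(schedule, "phase_schedule"))
  sowing <- as.Date(sowing); end <- as.Date(end)
  if (end < sowing) stop("season_gdd(): end precedes sowing", call. = FALSE)
  d <- weather_data(series)
  keep <- d$date >= sowing & d$date <= end
  sub <- d[keep, ]
  expected <- day_count_inclusive(sowing, end)
  if (nrow(sub) != expected) {
    stop("season_gdd(): series does not cover ", format(sowing), "..",
         format(end), " without gaps", call. = FALSE)
  }
  das <- day_count_inclusive(sowing, sub$date)
  idx <- findInterval(das, schedule$phases$start_day)
  gdd <- numeric(nrow(sub))
  ceiling_zeroed <- logical(nrow(sub))
  for (p in unique(idx)) {
    rows <- idx == p
    cc <- schedule$phases$cardinals[[p]]
    gdd[rows] <- daily_gdd(sub$tmax[rows], sub$tmin[rows], cc, method = method)
    ceiling_zeroed[rows] <- sub$tmax[rows] > cc$t_ceil
  }
  daily <- tibble::tibble(
    date = sub$date,
    day_after_sowing = das,
    phase = schedule$phases$label[idx],
    tmax = sub$tmax, tmin = sub$tmin,
    gdd = gdd, cum_gdd = cumsum(gdd))
  structure(
    list(daily = daily,
         total_gdd = sum(gdd),
         n_ceiling_days = sum(ceiling_zeroed),
         n_days_above_threshold = sum(sub$tmax > schedule$heat_zero_threshold),
         heat_zero_threshold = schedule$heat_zero_threshold),
    class = "gdd_result")
}

#' @export
print.gdd_result <- function(x, ...) {
  cat(sprintf(
    "<gdd_result> %d days, total %.1f degree-days; %d ceiling-zero day(s), %d day(s) Tmax > %.1f C\n",
    nrow(x$daily), x$total_gdd, x$n_ceiling_days, x$n_days_above_threshold,
    x$heat_zero_threshold))
  invisible(x)
}

#' First day after sowing at which cumulative GDD reaches a target
#'
#' Thermal-time phenology inversion: the day (inclusive convention, sowing
#' day = 1) on which the cumulative GDD first reaches `target_gdd`. If the
#' series ends before the target is met, the result is `NA` with attribute
#' `attained = FALSE` rather than an error, so callers can distinguish
#' non-attainment from bad input.
#'
#' @param series a [weather_series()].
#' @param sowing sowing date.
#' @param target_gdd positive target in degree-days (e.g. ~2200 for wheat
#'   maturity at a 4 C base).
#' @param schedule a [phase_schedule()].
#' @param end last date to consider (default: end of series).
#' @return Integer day after sowing, or `NA` (attribute `attained = FALSE`)
#'   if the accumulated total never reaches the target.
#' @export
days_to_reach <- function(series, sowing, target_gdd, schedule,
                          end = max(weather_data(series)$date)) {
  if (!is.numeric(target_gdd) || target_gdd <= 0) {
    stop("days_to_reach(): target_gdd must be > 0", call. = FALSE)
  }
  res <- season_gdd(series, sowing, schedule, end)
  hit <- which(res$daily$cum_gdd >= target_gdd)
  if (!length(hit)) {
    return(structure(NA_integer_, attained = FALSE))
  }
  structure(res$daily$day_after_sowing[hit[1]], attained = TRUE)
}
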