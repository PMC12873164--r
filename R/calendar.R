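#' Inclusive day count between two dates
#'
#' Counts calendar days from `start` to `end` with the start date counted as
#' day 1, the convention used throughout sowing-date arithmetic: a crop sown
#' on 15 October that reaches anthesis on 22 January has a days-to-anthesis
#' of 100. Leap years follow the real Gregorian calendar.
#'
#' @param start,end `Date` scalars (or vectors of equal length); `end` must
#'   not precede `start`.
#' @return Integer number of days, `>= 1`.
#' @examples
#' day_count_inclusive(as.Date("2021-10-15"), as.Date("2022-01-27")) # 105
#' @seealso [add_days_inclusive()] for the inverse operation.
#' @export
day_count_inclusive <- function(start, end) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (anyNA(start) || anyNA(end)) {
    stop("day_count_inclusive(): dates must not be NA", call. = FALSE)
  }
  if (any(end < start)) {
    stop("day_count_inclusive(): reversed interval (end precedes start)",
         call. = FALSE)
  }
  as.integer(end - start) + 1L
}

#' Date reached on day n, counting the start date as day 1
#'
#' Inverse of [day_count_inclusive()]: `add_days_inclusive(s, 1)` is `s`
#' itself, and `add_days_inclusive(s, day_count_inclusive(s, e))` is `e`.
#'
#' @param start `Date` scalar or vector.
#' @param n integer day index, `>= 1`.
#' @return A `Date`.
#' @examples
#' add_days_inclusive(as.Date("2021-10-15"), 100) # 2022-01-22
#' @export
add_days_inclusive <- function(start, n) {
  start <- as.Date(start)
  if (anyNA(start)) stop("add_days_inclusive(): start must not be NA", call. = FALSE)
  n <- as.integer(n)
  if (anyNA(n) || any(n < 1L)) {
    stop("add_days_inclusive(): n must be an integer >= 1 (day 1 = start)",
         call. = FALSE)
  }
  start + (n - 1L)
}

#' Growing-season window defined by month/day endpoints
#'
#' A season window is a pair of (month, day) endpoints, optionally spanning a
#' year boundary (as the default rabi wheat season, 15 October through
#' 30 April, does). The inclusive calendar length of the default window is
#' 198 days when February is non-leap and 199 otherwise.
#'
#' @param start_month,start_day,end_month,end_day integer calendar endpoints.
#' @param label character label for reports.
#' @return An object of class `season_window`.
#' @examples
#' season_window() # the default wheat season, 15 Oct - 30 Apr
#' @export
season_window <- function(start_month = 10L, start_day = 15L,
                          end_month = 4L, end_day = 30L,
                          label = "wheat season") {
  sm <- as.integer(start_month); sd <- as.integer(start_day)
  em <- as.integer(end_month); ed <- as.integer(end_day)
  for (v in list(sm, sd, em, ed)) {
    if (length(v) != 1L || is.na(v)) {
      stop("season_window(): endpoints must be scalar integers", call. = FALSE)
    }
  }
  if (sm < 1L || sm > 12L || em < 1L || em > 12L) {
    stop("season_window(): months must lie in 1..12", call. = FALSE)
  }
  # validate the day-of-month against a leap reference year so 29 Feb is legal
  chk <- function(m, d) {
    x <- as.Date(sprintf("2000-%02d-%02d", m, d))
    if (is.na(x)) stop("season_window(): invalid month/day pair", call. = FALSE)
  }
  chk(sm, sd); chk(em, ed)
  structure(
    list(start_month = sm, start_day = sd, end_month = em, end_day = ed,
         label = as.character(label)),
    class = "season_window"
  )
}

#' @export
print.season_window <- function(x, ...) {
  cat(sprintf("<season_window> %s: %02d-%02d .. %02d-%02d (%s)\n",
              x$label, x$start_month, x$start_day, x$end_month, x$end_day,
              if (spans_year_boundary(x)) "spans year boundary" else "within one year"))
  invisible(x)
}

spans_year_boundary <- function(window) {
  window$start_month > window$end_month ||
    (window$start_month == window$end_month && window$start_day > window$end_day)
}

#' Calendar dates of a season window for a given harvest year
#'
#' For a window spanning the year boundary, the start falls in
#' `harvest_year - 1` and the end in `harvest_year`; otherwise both fall in
#' `harvest_year`.
#'
#' @param window a [season_window()].
#' @param harvest_year integer year in which the season ends.
#' @return Named list with `Date` elements `start` and `end`.
#' @export
season_dates <- function(window, harvest_year) {
  stopifnot(inherits(window, "season_window"))
  harvest_year <- as.integer(harvest_year)
  start_year <- if (spans_year_boundary(window)) harvest_year - 1L else harvest_year
  start <- as.Date(sprintf("%04d-%02d-%02d", start_year,
                           window$start_month, window$start_day))
  end <- as.Date(sprintf("%04d-%02d-%02d", harvest_year,
                         window$end_month, window$end_day))
  if (is.na(start) || is.na(end)) {
    stop("season_dates(): window endpoints do not exist in this year ",
         "(29 February in a non-leap year?)", call. = FALSE)
  }
  list(start = start, end = end)
}
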