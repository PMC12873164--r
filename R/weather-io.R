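#' Read a daily weather table from delimited text
#'
#' Expects a header naming the date, tmax, tmin and rain columns; the column
#' names are configurable through `col_map`. Dates may be ISO (`%Y-%m-%d`) or
#' day-month-year (`%d-%m-%Y`, `%d/%m/%Y`); the format is auto-detected from
#' the first row and applied to all rows.
#'
#' @param path file path.
#' @param col_map named character vector mapping the canonical names
#'   (`date`, `tmax`, `tmin`, `rain`) to the file's column names.
#' @param sep field separator (default comma).
#' @param site_id,latitude,longitude site metadata; if a JSON sidecar
#'   (`<path>.site.json`) written by [write_weather_table()] exists, its
#'   values are used as defaults.
#' @param strict passed to [weather_series()]; in strict mode a row with
#'   `tmax < tmin` is an error naming the row.
#' @return A [weather_series()].
#' @export
read_weather_table <- function(path,
                               col_map = c(date = "date", tmax = "tmax",
                                           tmin = "tmin", rain = "rain"),
                               sep = ",",
                               site_id = NULL, latitude = NULL, longitude = NULL,
                               strict = TRUE) {
  if (!file.exists(path)) stop("read_weather_table(): no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("date", "tmax", "tmin", "rain")
  if (!all(need %in% names(col_map))) {
    stop("read_weather_table(): col_map must name date, tmax, tmin, rain", call. = FALSE)
  }
  missing_cols <- setdiff(unname(col_map[need]), names(raw))
  if (length(missing_cols)) {
    stop("read_weather_table(): missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dates <- parse_weather_dates(as.character(raw[[col_map[["date"]]]]))
  df <- data.frame(date = dates,
                   tmax = as.numeric(raw[[col_map[["tmax"]]]]),
                   tmin = as.numeric(raw[[col_map[["tmin"]]]]),
                   rain = as.numeric(raw[[col_map[["rain"]]]]))

  side <- read_site_sidecar(path)
  meta <- list(site_id = site_id %||% side$site_id %||% "site",
               latitude = latitude %||% side$latitude %||% NA_real_,
               longitude = longitude %||% side$longitude %||% NA_real_)

  bad <- which(!is.na(df$tmax) & !is.na(df$tmin) & df$tmax < df$tmin)
  if (strict && length(bad)) {
    stop("read_weather_table(): tmax < tmin at data row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), " of ", path, call. = FALSE)
  }
  weather_series(df, site_id = meta$site_id, latitude = meta$latitude,
                 longitude = meta$longitude, strict = strict)
}

parse_weather_dates <- function(x) {
  first <- x[!is.na(x) & nzchar(x)][1]
  if (is.na(first)) stop("read_weather_table(): no parseable dates", call. = FALSE)
  # detect the layout structurally; strptime alone would accept a 2-digit
  # "year" for %Y and silently mis-read day-month-year files
  fmt <- if (grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", first)) {
    "%Y-%m-%d"
  } else if (grepl("^\\d{1,2}-\\d{1,2}-\\d{4}$", first)) {
    "%d-%m-%Y"
  } else if (grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", first)) {
    "%d/%m/%Y"
  } else NULL
  if (is.null(fmt)) {
    stop("read_weather_table(): unrecognised date format at line 2: '", first,
         "' (expected ISO or day-month-year)", call. = FALSE)
  }
  out <- as.Date(x, format = fmt)
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("read_weather_table(): unparseable date '", x[bad],
         "' at data row ", bad, call. = FALSE)
  }
  out
}

#' Write a weather series as CSV plus a JSON site-metadata sidecar
#'
#' Values are written at 0.1 precision (the precision the round-trip tests
#' guarantee); site id and coordinates go to `<path>.site.json` so that
#' [read_weather_table()] can restore them.
#'
#' @param series a [weather_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_table <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  d <- weather_data(series)
  out <- data.frame(date = format(d$date, "%Y-%m-%d"),
                    tmax = sprintf("%.1f", d$tmax),
                    tmin = sprintf("%.1f", d$tmin),
                    rain = sprintf("%.1f", d$rain))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(site_id = series$site_id, latitude = series$latitude,
               longitude = series$longitude)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".site.json")

read_site_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Missing-value code used for solar radiation, which the generator does not
# model; fixed-width station files carry it as a placeholder.
WTH_SRAD_MISSING <- -99.0

#' Write a DSSAT-style fixed-width daily weather file (.WTH)
#'
#' Station header carries site id and coordinates; data columns are DATE
#' (YYDDD), SRAD, TMAX, TMIN, RAIN. Solar radiation is not modelled and is
#' written as the missing code -99.0. Temperatures and rainfall are written
#' at 0.1 precision.
#'
#' @param series a [weather_series()] with non-missing coordinates.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_wth()] for the matching reader.
#' @export
write_wth <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  d <- weather_data(series)
  if (nrow(d) == 0L) stop("write_wth(): empty series", call. = FALSE)
  if (is.na(series$latitude) || is.na(series$longitude)) {
    stop("write_wth(): site coordinates are required for a station file",
         call. = FALSE)
  }
  insi <- toupper(substr(gsub("[^A-Za-z0-9]", "", series$site_id), 1L, 4L))
  if (!nzchar(insi)) insi <- "SITE"
  yyddd <- sprintf("%02d%03d",
                   as.integer(format(d$date, "%y")),
                   as.integer(format(d$date, "%j")))
  lines <- c(
    sprintf("*WEATHER DATA : %s", series$site_id),
    "",
    "@ INSI      LAT     LONG  ELEV   TAV   AMP REFHT WNDHT",
    sprintf("  %-4s %8.3f %8.3f   -99 -99.0 -99.0 -99.0 -99.0",
            insi, series$latitude, series$longitude),
    "@DATE  SRAD  TMAX  TMIN  RAIN",
    sprintf("%s %5.1f %5.1f %5.1f %5.1f",
            yyddd, WTH_SRAD_MISSING, d$tmax, d$tmin, d$rain)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a DSSAT-style .WTH file written by [write_wth()]
#'
#' Two-digit years in the DATE column are expanded with a pivot: values
#' `<= 49` map to 20xx, values `>= 50` to 19xx (covering 1950-2049, ample
#' for 1980-2020 station records).
#'
#' @param path path to a .WTH file.
#' @param strict passed to [weather_series()].
#' @return A [weather_series()].
#' @export
read_wth <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("read_wth(): no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  site_id <- sub("^\\*WEATHER DATA : ", "", lines[grepl("^\\*WEATHER DATA", lines)][1])
  hdr_at <- which(grepl("^@ INSI", lines))
  if (!length(hdr_at)) stop("read_wth(): station header not found in ", path, call. = FALSE)
  stn <- strsplit(trimws(lines[hdr_at + 1L]), "\\s+")[[1]]
  lat <- as.numeric(stn[2]); lon <- as.numeric(stn[3])
  data_at <- which(grepl("^@DATE", lines))
  body <- lines[seq(data_at + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "\\s+")
  yyddd <- vapply(fields, `[[`, character(1), 1L)
  yy <- as.integer(substr(yyddd, 1L, 2L))
  ddd <- as.integer(substr(yyddd, 3L, 5L))
  year <- ifelse(yy <= 49L, 2000L + yy, 1900L + yy)
  dates <- as.Date(sprintf("%04d-01-01", year)) + (ddd - 1L)
  df <- data.frame(
    date = dates,
    tmax = as.numeric(vapply(fields, `[[`, character(1), 3L)),
    tmin = as.numeric(vapply(fields, `[[`, character(1), 4L)),
    rain = as.numeric(vapply(fields, `[[`, character(1), 5L)))
  weather_series(df, site_id = site_id, latitude = lat, longitude = lon,
                 strict = strict)
}
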