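#' Descriptive statistics in the survey-table convention
#'
#' The eight statistics of a station-climatology table: range, minimum,
#' maximum, mean, standard deviation, variance, skewness and kurtosis.
#' Variance and SD use the sample (n - 1) denominator; skewness is the
#' adjusted Fisher-Pearson coefficient and kurtosis is excess kurtosis
#' (normal = 0), both in the SPSS/Statgraphics convention (`e1071` type 2).
#' The adjusted estimators are undefined below n = 3 (skewness) and n = 4
#' (kurtosis); those entries are `NA` for shorter inputs.
#'
#' @param values numeric vector, `n >= 2`, all finite.
#' @param strict if `TRUE` (default) a zero-variance vector is an error
#'   (its skewness/kurtosis are undefined); if `FALSE` a flagged
#'   zero-variance row is returned with `NA` shape statistics.
#' @return A one-row tibble with columns `n`, `range`, `minimum`, `maximum`,
#'   `mean`, `sd`, `variance`, `skewness`, `kurtosis`, `zero_variance`.
#' @examples
#' describe(c(2, 4, 6)) # mean 4, sd 2, variance 4
#' @export
describe <- function(values, strict = TRUE) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("describe(): need n >= 2", call. = FALSE)
  if (any(!is.finite(values))) stop("describe(): non-finite values", call. = FALSE)
  s <- stats::sd(values)
  zero_var <- s == 0
  if (zero_var && strict) {
    stop("describe(): zero-variance input; shape statistics undefined ",
         "(use strict = FALSE to flag instead)", call. = FALSE)
  }
  tibble::tibble(
    n = length(values),
    range = max(values) - min(values),
    minimum = min(values),
    maximum = max(values),
    mean = mean(values),
    sd = s,
    variance = s^2,
    skewness = if (zero_var || length(values) < 3L) NA_real_ else
      e1071::skewness(values, type = 2),
    kurtosis = if (zero_var || length(values) < 4L) NA_real_ else
      e1071::kurtosis(values, type = 2),
    zero_variance = zero_var)
}

#' Polynomial trend regression
#'
#' Least-squares fit of `y = b0 + b1*x + ... + bn*x^n + e` (raw, not
#' orthogonal, polynomial basis), with R-squared against the mean model and
#' the overall-F p-value. Degree 2 is the conventional choice for decadal
#' climate/phenology trends; degree 1 gives the plain linear trend.
#'
#' @param x,y numeric vectors of equal length; `length(x) > degree + 1`.
#' @param degree polynomial degree, `>= 1` (default 2).
#' @return An object of class `poly_fit`: list with `degree`,
#'   `coefficients` (b0..bn), `r_squared`, `p_value`, `residual_sd`,
#'   `fitted`, `residuals`, and the underlying `lm` object in `$model`.
#' @examples
#' f <- fit_polynomial(1:10, 2 * (1:10) + 1, degree = 1)
#' f$coefficients # 1, 2
#' @export
fit_polynomial <- function(x, y, degree = 2L) {
  x <- as.numeric(x); y <- as.numeric(y)
  degree <- as.integer(degree)
  if (degree < 1L) stop("fit_polynomial(): degree must be >= 1", call. = FALSE)
  if (length(x) != length(y)) stop("fit_polynomial(): length mismatch", call. = FALSE)
  if (length(x) <= degree + 1L) {
    stop("fit_polynomial(): need n > degree + 1 observations", call. = FALSE)
  }
  if (length(unique(x)) <= degree) {
    stop("fit_polynomial(): rank deficiency - fewer than degree + 1 distinct ",
         "x values", call. = FALSE)
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  sm <- summary(fit)
  p_value <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  structure(
    list(degree = degree,
         coefficients = stats::setNames(coefs, paste0("b", 0:degree)),
         r_squared = sm$r.squared,
         p_value = p_value,
         residual_sd = sm$sigma,
         fitted = unname(stats::fitted(fit)),
         residuals = unname(stats::residuals(fit)),
         model = fit),
    class = "poly_fit")
}

#' @export
print.poly_fit <- function(x, ...) {
  terms <- paste(sprintf("%.4g%s", x$coefficients,
                         c("", "*x", paste0("*x^", seq_len(x$degree))[-1])),
                 collapse = " + ")
  cat(sprintf("<poly_fit> degree %d: y = %s\n  R^2 %.4f, F-test p %.3g, residual sd %.4g\n",
              x$degree, terms, x$r_squared, x$p_value, x$residual_sd))
  invisible(x)
}

#' Evaluate a fitted polynomial at new x
#' @param fit a [fit_polynomial()] result.
#' @param x numeric vector.
#' @return Fitted values.
#' @export
predict_polynomial <- function(fit, x) {
  stopifnot(inherits(fit, "poly_fit"))
  drop(outer(as.numeric(x), 0:fit$degree, `^`) %*% fit$coefficients)
}

#' Per-decade minimum, maximum and mean of an annual series
#'
#' Partitions years by half-open decade edges `[e1, e2), [e2, e3), ...` and
#' summarises each. Empty decades are kept as flagged `NA` rows rather than
#' silently dropped.
#'
#' @param years integer years.
#' @param values numeric values aligned with `years`.
#' @param edges increasing integer decade edges; the final edge closes the
#'   last decade (its right endpoint is inclusive so a closing year like
#'   2020 belongs to the last decade).
#' @return A tibble with `decade` label, `n`, `min`, `max`, `mean` and a
#'   formatted `value_range` string ("min-max").
#' @export
decadal_summary <- function(years, values,
                            edges = c(1980L, 1990L, 2000L, 2010L, 2021L)) {
  years <- as.integer(years); values <- as.numeric(values)
  if (length(years) != length(values)) {
    stop("decadal_summary(): length mismatch", call. = FALSE)
  }
  edges <- sort(as.integer(edges))
  if (length(edges) < 2L) stop("decadal_summary(): need >= 2 edges", call. = FALSE)
  bin <- findInterval(years, edges, rightmost.closed = TRUE)
  in_range <- bin >= 1L & bin < length(edges)
  rows <- lapply(seq_len(length(edges) - 1L), function(k) {
    v <- values[in_range & bin == k]
    lab <- sprintf("%d-%d", edges[k],
                   if (k == length(edges) - 1L) edges[k + 1L] else edges[k + 1L] - 1L)
    if (!length(v)) {
      tibble::tibble(decade = lab, n = 0L, min = NA_real_, max = NA_real_,
                     mean = NA_real_, value_range = NA_character_,
                     empty = TRUE)
    } else {
      tibble::tibble(decade = lab, n = length(v), min = min(v), max = max(v),
                     mean = mean(v),
                     value_range = sprintf("%g-%g", min(v), max(v)),
                     empty = FALSE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Pearson correlation matrix of agro-meteorological variables
#'
#' @param columns a data frame or named list of equal-length numeric
#'   vectors, `n >= 3`.
#' @return A symmetric correlation matrix with unit diagonal, class
#'   `matrix`.
#' @export
pearson_matrix <- function(columns) {
  df <- as.data.frame(columns)
  if (ncol(df) < 2L) stop("pearson_matrix(): need >= 2 columns", call. = FALSE)
  if (nrow(df) < 3L) stop("pearson_matrix(): need n >= 3", call. = FALSE)
  if (any(!vapply(df, is.numeric, logical(1)))) {
    stop("pearson_matrix(): all columns must be numeric", call. = FALSE)
  }
  sds <- vapply(df, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("pearson_matrix(): zero-variance column(s): ",
         paste(names(df)[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::cor(df, method = "pearson")
}
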