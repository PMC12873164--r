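#' Observed-versus-simulated agreement statistics
#'
#' The standard crop-model evaluation set over paired observed (`O`) and
#' simulated (`S`) values:
#' \itemize{
#'   \item `r_squared`: squared Pearson correlation of O and S (the printed
#'     formula of validation tables); `r_squared_model = 1 - SSE/SST` of the
#'     1:1 comparison is also reported, and the two differ under bias.
#'   \item `rmse = sqrt(mean((S - O)^2))`, `mae = mean(|S - O|)`.
#'   \item `bias = mean(S - O)` - positive means over-simulation.
#'   \item slope `b` and intercept `a` of the regression `S = a + b O`,
#'     read against the 1:1 line.
#' }
#' Identities: `rmse >= mae`, `rmse >= |bias|`, and
#' `rmse^2 = bias^2 + var_pop(S - O)`.
#'
#' @param observed,simulated numeric vectors of equal length, `n >= 2`,
#'   finite. The observed vector must not be constant (correlation and
#'   slope are undefined).
#' @return A one-row tibble with `n`, `r_squared`, `r_squared_model`,
#'   `rmse`, `mae`, `bias`, `slope_b`, `intercept_a`.
#' @examples
#' evaluate_pairs(c(1, 2, 3), c(2, 3, 4)) # bias 1, RMSE 1, R^2 1, b 1, a 1
#' @export
evaluate_pairs <- function(observed, simulated) {
  o <- as.numeric(observed); s <- as.numeric(simulated)
  if (length(o) != length(s)) stop("evaluate_pairs(): length mismatch", call. = FALSE)
  if (length(o) < 2L) stop("evaluate_pairs(): need n >= 2 pairs", call. = FALSE)
  if (any(!is.finite(o)) || any(!is.finite(s))) {
    stop("evaluate_pairs(): non-finite values", call. = FALSE)
  }
  if (stats::sd(o) == 0) {
    stop("evaluate_pairs(): constant observed vector - r_squared, slope_b ",
         "and intercept_a are undefined", call. = FALSE)
  }
  err <- s - o
  r2 <- if (stats::sd(s) == 0) 0 else stats::cor(o, s)^2
  sse <- sum(err^2)
  sst <- sum((o - mean(o))^2)
  fit <- stats::lm(s ~ o)
  tibble::tibble(
    n = length(o),
    r_squared = r2,
    r_squared_model = 1 - sse / sst,
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    bias = mean(err),
    slope_b = unname(stats::coef(fit)[2]),
    intercept_a = unname(stats::coef(fit)[1]))
}
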