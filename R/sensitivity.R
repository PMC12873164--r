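#' Surrogate yield model for temperature and CO2 sensitivity
#'
#' A deliberately simple, documented response surface used to exercise the
#' sensitivity statistics in place of a process-based crop simulator:
#' `yield = baseline * (1 - temp_loss_rate * dT) * (1 + co2_response *
#' ln(C / co2_reference)) + noise`, floored at zero. It is a surrogate: a
#' multiplicative linear-loss x log-CO2 shape, never a claim about crop
#' physiology. Default calibrations: Islamabad baseline 4.0 t/ha with 4.5 %
#' loss per degree C; Chakwal 4.0 t/ha with 6 % per degree C.
#'
#' @param baseline_yield ambient yield, t/ha, > 0.
#' @param temp_loss_rate fractional yield loss per degree C warming, in
#'   `[0, 1)`.
#' @param co2_response fractional yield gain per log-unit CO2.
#' @param co2_reference reference CO2 concentration, ppm (default 350).
#' @param noise_sd additive yield noise SD, t/ha (>= 0).
#' @return An object of class `surrogate_yield_model`.
#' @export
surrogate_yield_model <- function(baseline_yield = 4.0,
                                  temp_loss_rate = 0.045,
                                  co2_response = 0.08,
                                  co2_reference = 350,
                                  noise_sd = 0) {
  if (baseline_yield <= 0) stop("surrogate_yield_model(): baseline must be > 0",
                                call. = FALSE)
  if (temp_loss_rate < 0 || temp_loss_rate >= 1) {
    stop("surrogate_yield_model(): temp_loss_rate must lie in [0, 1)", call. = FALSE)
  }
  if (co2_reference <= 0) stop("surrogate_yield_model(): co2_reference must be > 0",
                               call. = FALSE)
  if (noise_sd < 0) stop("surrogate_yield_model(): noise_sd must be >= 0",
                         call. = FALSE)
  structure(list(baseline_yield = as.numeric(baseline_yield),
                 temp_loss_rate = as.numeric(temp_loss_rate),
                 co2_response = as.numeric(co2_response),
                 co2_reference = as.numeric(co2_reference),
                 noise_sd = as.numeric(noise_sd)),
            class = "surrogate_yield_model")
}

#' @rdname surrogate_yield_model
#' @param site `"islamabad"` or `"chakwal"`.
#' @param ... overrides for any field.
#' @export
surrogate_preset <- function(site = c("islamabad", "chakwal"), ...) {
  site <- match.arg(site)
  rate <- if (site == "islamabad") 0.045 else 0.06
  args <- utils::modifyList(
    list(baseline_yield = 4.0, temp_loss_rate = rate, co2_response = 0.08,
         co2_reference = 350, noise_sd = 0),
    list(...))
  do.call(surrogate_yield_model, args)
}

#' @export
print.surrogate_yield_model <- function(x, ...) {
  cat(sprintf(
    "<surrogate_yield_model> baseline %.2f t/ha, -%.1f %%/C, +%.1f %%/log-CO2 (ref %.0f ppm), noise sd %.2f\n",
    x$baseline_yield, 100 * x$temp_loss_rate, 100 * x$co2_response,
    x$co2_reference, x$noise_sd))
  invisible(x)
}

# Deterministic part of the surrogate response.
surrogate_mean_yield <- function(model, delta_t, co2) {
  model$baseline_yield *
    (1 - model$temp_loss_rate * delta_t) *
    (1 + model$co2_response * log(co2 / model$co2_reference))
}

#' Percentage yield loss per degree C of warming
#'
#' `(y_ambient - y_warmed) / y_ambient * 100`, divided by the temperature
#' increment when it exceeds 1 C. When vectors are supplied (yields at
#' successive increments), the per-degree losses are averaged, giving the
#' "average yield reduction rate per degree C".
#'
#' @param y_ambient baseline yield(s), t/ha, > 0.
#' @param y_warmed perturbed yield(s), t/ha, aligned with `y_ambient`.
#' @param delta_t temperature increment(s) in degrees C (default 1).
#' @return Mean percentage loss per degree C.
#' @examples
#' yield_loss_per_degC(4.00, 3.82) # 4.5
#' @export
yield_loss_per_degC <- function(y_ambient, y_warmed, delta_t = 1) {
  y_ambient <- as.numeric(y_ambient); y_warmed <- as.numeric(y_warmed)
  if (any(y_ambient <= 0)) stop("yield_loss_per_degC(): non-positive ambient yield",
                                call. = FALSE)
  delta_t <- rep_len(as.numeric(delta_t), length(y_warmed))
  if (any(delta_t <= 0)) stop("yield_loss_per_degC(): delta_t must be > 0",
                              call. = FALSE)
  mean((y_ambient - y_warmed) / y_ambient * 100 / delta_t)
}

#' Percentage yield change under elevated CO2
#'
#' `(y_elev - y_base) / y_base * 100`; positive when CO2 fertilisation
#' raises yield. Expressed per 100 ppm by dividing by
#' `(co2_elev - co2_base) / 100` when the concentrations are supplied.
#'
#' @param y_base yield at the reference CO2 level, t/ha, > 0.
#' @param y_elev yield at the elevated level, t/ha.
#' @param co2_base,co2_elev optional concentrations (ppm); when given, the
#'   change is scaled to percent per 100 ppm.
#' @return Percentage change (per 100 ppm if concentrations supplied).
#' @examples
#' yield_change_per_co2(4.0, 4.3) # 7.5
#' @export
yield_change_per_co2 <- function(y_base, y_elev, co2_base = NULL,
                                 co2_elev = NULL) {
  y_base <- as.numeric(y_base); y_elev <- as.numeric(y_elev)
  if (any(y_base <= 0)) stop("yield_change_per_co2(): non-positive base yield",
                             call. = FALSE)
  pct <- (y_elev - y_base) / y_base * 100
  if (!is.null(co2_base) && !is.null(co2_elev)) {
    step <- (as.numeric(co2_elev) - as.numeric(co2_base)) / 100
    if (any(step == 0)) stop("yield_change_per_co2(): zero CO2 increment",
                             call. = FALSE)
    pct <- pct / step
  }
  mean(pct)
}

#' Simulate a temperature x CO2 sensitivity grid
#'
#' Runs the surrogate model over every (delta-T, CO2) cell with `replicates`
#' noisy draws per cell, reproducibly from `seed`. Yields are floored at
#' zero.
#'
#' @param model a [surrogate_yield_model()].
#' @param deltas temperature increments, degrees C (default 0..8).
#' @param co2_levels CO2 concentrations, ppm (default 350 to 800 by 50).
#' @param replicates draws per cell (>= 1).
#' @param seed integer seed.
#' @return An object of class `sensitivity_grid`: list with `cells` (tibble
#'   of delta_t, co2, rep, yield), the `model`, and `summary` (per-cell
#'   min/q1/median/q3/max/mean boxplot statistics).
#' @export
run_grid <- function(model, deltas = 0:8,
                     co2_levels = seq(350, 800, by = 50),
                     replicates = 1L, seed = 1L) {
  stopifnot(inherits(model, "surrogate_yield_model"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("run_grid(): replicates must be >= 1", call. = FALSE)
  deltas <- as.numeric(deltas); co2_levels <- as.numeric(co2_levels)
  if (!length(deltas) || !length(co2_levels) || anyNA(deltas) || anyNA(co2_levels)) {
    stop("run_grid(): malformed grid", call. = FALSE)
  }
  if (any(co2_levels <= 0)) stop("run_grid(): CO2 levels must be > 0", call. = FALSE)
  grid <- expand.grid(rep = seq_len(replicates), delta_t = deltas,
                      co2 = co2_levels, KEEP.OUT.ATTRS = FALSE)
  mu <- surrogate_mean_yield(model, grid$delta_t, grid$co2)
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(nrow(grid), 0, model$noise_sd))
  cells <- tibble::tibble(delta_t = grid$delta_t, co2 = grid$co2,
                          rep = grid$rep, yield = pmax(mu + noise, 0))
  summary <- dplyr::summarise(
    dplyr::group_by(cells, delta_t, co2),
    min = min(yield), q1 = stats::quantile(yield, 0.25),
    median = stats::median(yield),
    q3 = stats::quantile(yield, 0.75),
    max = max(yield), mean = mean(yield), .groups = "drop")
  structure(list(cells = cells, model = model, summary = summary),
            class = "sensitivity_grid")
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("<sensitivity_grid> %d delta-T x %d CO2 cells, %d replicate(s)/cell\n",
              length(unique(x$cells$delta_t)), length(unique(x$cells$co2)),
              max(x$cells$rep)))
  invisible(x)
}

#' Sensitivity statistics from a simulated grid
#'
#' Estimates the average percentage yield loss per degree C (from the
#' reference-CO2 column of the grid, successive increments against the
#' ambient cell) and the average percentage yield change per 100 ppm CO2
#' (from the ambient-temperature row against the reference CO2 cell).
#'
#' @param grid a [run_grid()] result.
#' @param co2_ref reference CO2 for the temperature sweep (default: the
#'   model's reference, or the lowest level in the grid if absent).
#' @return A one-row tibble with `yield_loss_pct_per_degC` and
#'   `yield_change_pct_per_100ppm`.
#' @export
grid_stats <- function(grid, co2_ref = NULL) {
  stopifnot(inherits(grid, "sensitivity_grid"))
  cells <- grid$cells
  co2s <- sort(unique(cells$co2))
  if (is.null(co2_ref)) {
    co2_ref <- if (grid$model$co2_reference %in% co2s)
      grid$model$co2_reference else co2s[1]
  }
  deltas <- sort(unique(cells$delta_t))
  base_t <- deltas[1]
  cell_mean <- function(dt, c) mean(cells$yield[cells$delta_t == dt & cells$co2 == c])
  y0 <- cell_mean(base_t, co2_ref)
  warm <- deltas[deltas > base_t]
  loss <- if (length(warm)) {
    yield_loss_per_degC(y0, vapply(warm, cell_mean, numeric(1), c = co2_ref),
                        delta_t = warm - base_t)
  } else NA_real_
  elev <- co2s[co2s > co2_ref]
  change <- if (length(elev)) {
    yield_change_per_co2(y0, vapply(elev, function(c) cell_mean(base_t, c),
                                    numeric(1)),
                         co2_base = co2_ref, co2_elev = elev)
  } else NA_real_
  tibble::tibble(yield_loss_pct_per_degC = loss,
                 yield_change_pct_per_100ppm = change)
}

#' Shift a weather series by a uniform temperature delta
#'
#' Adds `delta` to both Tmax and Tmin of every day; rainfall is untouched.
#' Used to build warming scenarios relative to a historical baseline.
#'
#' @param series a [weather_series()].
#' @param delta degrees C, finite.
#' @return A new `weather_series`.
#' @export
apply_delta_t <- function(series, delta) {
  stopifnot(inherits(series, "weather_series"))
  delta <- as.numeric(delta)
  if (!is.finite(delta)) stop("apply_delta_t(): delta must be finite", call. = FALSE)
  out <- series
  out$data$tmax <- out$data$tmax + delta
  out$data$tmin <- out$data$tmin + delta
  out
}
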