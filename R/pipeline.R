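#' Derive a phenology/yield table from a weather series by thermal time
#'
#' For each fully covered season: days to anthesis (DTA) is the first day
#' whose cumulative vegetative-phase GDD reaches `anthesis_gdd`; days to
#' maturity (DTM) the first day the full three-phase accumulation (phase
#' boundaries set by that season's DTA) reaches `maturity_gdd`. Seasons that
#' never attain a target are capped at the season length and flagged. Grain
#' yield is a transparent linear response to the seasonal mean-temperature
#' anomaly: `baseline_yield * (1 - temp_loss_rate * (tmean - ref_tmean))`,
#' floored at zero - warm seasons mature earlier and yield less, which is
#' the coupling the trend analyses exercise.
#'
#' @param series a multi-season [weather_series()].
#' @param window a [season_window()].
#' @param anthesis_gdd,maturity_gdd thermal targets in degree-days.
#' @param flowering_duration days of the anthesis-to-grain-fill phase.
#' @param baseline_yield,temp_loss_rate,ref_tmean yield-response parameters
#'   (t/ha, fraction per degree C, degrees C). `ref_tmean = NULL` uses the
#'   series' own long-term seasonal mean.
#' @return A tibble with `harvest_year`, `dta`, `dtm`, `grain_yield`,
#'   `season_tmean`, `season_rain`, `total_gdd`, `n_days_above_threshold`,
#'   `attained` (both thermal targets met).
#' @export
phenology_from_weather <- function(series, window = season_window(),
                                   anthesis_gdd = 1340, maturity_gdd = 1550,
                                   flowering_duration = 10L,
                                   baseline_yield = 4.0,
                                   temp_loss_rate = 0.045,
                                   ref_tmean = NULL) {
  seas <- seasonal_summary(series, window)
  if (is.null(ref_tmean)) ref_tmean <- mean(seas$season_tmean)
  veg_only <- phase_schedule(tibble::tibble(
    label = "vegetative", start_day = 1L,
    cardinals = list(wheat_cardinals("vegetative"))))
  rows <- lapply(seq_len(nrow(seas)), function(i) {
    y <- seas$harvest_year[i]
    s <- extract_season(series, window, y)
    ends <- season_dates(window, y)
    dta <- days_to_reach(s, ends$start, anthesis_gdd, veg_only, end = ends$end)
    dta_ok <- isTRUE(attr(dta, "attained"))
    if (!dta_ok) dta <- seas$n_days[i]
    sched <- wheat_schedule(as.integer(dta), flowering_duration)
    dtm <- days_to_reach(s, ends$start, maturity_gdd, sched, end = ends$end)
    dtm_ok <- isTRUE(attr(dtm, "attained"))
    if (!dtm_ok) dtm <- seas$n_days[i]
    res <- season_gdd(s, ends$start, sched, ends$end)
    tibble::tibble(
      harvest_year = y,
      dta = as.integer(dta),
      dtm = max(as.integer(dtm), as.integer(dta) + 1L),
      grain_yield = max(baseline_yield *
                          (1 - temp_loss_rate * (seas$season_tmean[i] - ref_tmean)), 0),
      season_tmean = seas$season_tmean[i],
      season_rain = seas$season_rain[i],
      total_gdd = res$total_gdd,
      n_days_above_threshold = res$n_days_above_threshold,
      attained = dta_ok && dtm_ok)
  })
  dplyr::bind_rows(rows)
}

default_run_config <- function() {
  list(site = "islamabad",
       start_year = 1980L, end_year = 2020L,
       seed = NULL,
       season = list(start_month = 10L, start_day = 15L,
                     end_month = 4L, end_day = 30L),
       phenology = list(anthesis_gdd = 1340, maturity_gdd = 1550,
                        flowering_duration = 10L),
       scenarios = list(yield_losses = NULL),
       sensitivity = list(deltas = 0:8,
                          co2_levels = seq(350, 800, by = 50),
                          replicates = 100L, noise_sd = 0.3),
       trend_degree = 2L)
}

#' Run the full agro-climatic pipeline
#'
#' Chains every stage into one reproducible bundle: synthetic weather
#' generation, season extraction and GDD accumulation, thermal-time
#' phenology, descriptive statistics, polynomial trends and the correlation
#' matrix, the sowing-date scenario and stage-rainfall tables, the
#' temperature x CO2 sensitivity grid with its summary statistics, and
#' observed-vs-simulated evaluation metrics on the phenology table. All
#' outputs are plain CSV/JSON files; a manifest records the config (and its
#' hash), seed and package version, so an identical config + seed
#' regenerates a byte-identical bundle.
#'
#' @param config a named list (missing fields take defaults), or the path
#'   to a YAML file with the same structure. Recognised top-level fields:
#'   `site` (preset name) or `climate` (explicit [climate_gen_config()]
#'   fields), `start_year`, `end_year`, `seed` (mandatory), `season`,
#'   `phenology`, `scenarios`, `sensitivity`, `trend_degree`.
#' @param out_dir output directory, created if needed.
#' @param quiet suppress stage log messages (written to stderr).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$seed)) {
    stop("run_pipeline(): a seed is mandatory for synthetic runs", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[wheatclim] ", fmt), ...))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("%-12s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  window <- do.call(season_window, cfg$season)

  series <- stage("weather", {
    gen_cfg <- if (!is.null(cfg$climate)) {
      do.call(climate_gen_config,
              utils::modifyList(cfg$climate,
                                list(start_year = cfg$start_year,
                                     end_year = cfg$end_year,
                                     seed = cfg$seed)))
    } else {
      site_preset(cfg$site, start_year = cfg$start_year,
                  end_year = cfg$end_year, seed = cfg$seed)
    }
    s <- generate_series(gen_cfg)
    write_weather_table(s, file.path(out_dir, "weather.csv"))
    write_wth(s, file.path(out_dir, "weather.wth"))
    s
  })

  phen <- stage("phenology", {
    p <- do.call(phenology_from_weather,
                 c(list(series = series, window = window), cfg$phenology))
    write_csv_plain(p, file.path(out_dir, "phenology.csv"))
    p
  })

  trends <- stage("trends", {
    vars <- c("season_tmean", "season_rain", "total_gdd", "dta", "dtm",
              "grain_yield")
    desc <- dplyr::bind_rows(lapply(vars, function(v) {
      cbind(tibble::tibble(variable = v), describe(phen[[v]]))
    }))
    write_csv_plain(desc, file.path(out_dir, "descriptive_stats.csv"))
    fits <- lapply(vars, function(v) {
      f <- fit_polynomial(phen$harvest_year, phen[[v]], degree = cfg$trend_degree)
      list(variable = v, degree = f$degree,
           coefficients = as.list(f$coefficients),
           r_squared = f$r_squared, p_value = f$p_value,
           residual_sd = f$residual_sd)
    })
    jsonlite::write_json(fits, file.path(out_dir, "trend_fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    dec <- decadal_summary(phen$harvest_year, phen$dta,
                           edges = decade_edges(cfg$start_year, cfg$end_year))
    write_csv_plain(dec, file.path(out_dir, "decadal_dta.csv"))
    cm <- pearson_matrix(phen[vars])
    utils::write.csv(round(cm, 6), file.path(out_dir, "correlation.csv"))
    list(descriptives = desc, fits = fits, decadal_dta = dec, correlation = cm)
  })

  scen <- stage("scenarios", {
    site <- if (!is.null(cfg$site) && cfg$site %in% c("islamabad", "chakwal"))
      cfg$site else "islamabad"
    sc_list <- standard_scenarios(site)
    tab <- scenario_table(series, sc_list,
                          yield_losses = cfg$scenarios$yield_losses)
    write_csv_plain(tab, file.path(out_dir, "scenario_table.csv"))
    dta_fixed <- sc_list[[1]]$dta_days
    rain <- stage_rainfall(series, dta_fixed, window,
                           edges = decade_edges(cfg$start_year, cfg$end_year))
    write_csv_plain(rain, file.path(out_dir, "stage_rainfall.csv"))
    list(table = tab, rainfall = rain)
  })

  sens <- stage("sensitivity", {
    site <- if (!is.null(cfg$site) && cfg$site %in% c("islamabad", "chakwal"))
      cfg$site else "islamabad"
    model <- surrogate_preset(site, noise_sd = cfg$sensitivity$noise_sd)
    grid <- run_grid(model, deltas = cfg$sensitivity$deltas,
                     co2_levels = cfg$sensitivity$co2_levels,
                     replicates = cfg$sensitivity$replicates,
                     seed = cfg$seed)
    write_csv_plain(grid$summary, file.path(out_dir, "sensitivity_cells.csv"))
    stats <- grid_stats(grid)
    jsonlite::write_json(as.list(stats),
                         file.path(out_dir, "sensitivity_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(grid = grid, stats = stats)
  })

  evalm <- stage("evaluate", {
    # agreement between the thermal-time DTA and the linear trend fit of it:
    # a self-contained observed-vs-simulated demonstration of the metrics
    f <- fit_polynomial(phen$harvest_year, phen$dta, degree = 1L)
    m <- evaluate_pairs(phen$dta, f$fitted)
    jsonlite::write_json(as.list(m), file.path(out_dir, "eval_metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  manifest <- stage("manifest", {
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    man <- list(
      package = "wheatclim",
      version = as.character(utils::packageVersion("wheatclim")),
      seed = cfg$seed,
      config_file = "config.json",
      config_md5 = unname(tools::md5sum(cfg_path)),
      outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(series = series, phenology = phen, trends = trends,
                 scenarios = scen, sensitivity = sens, evaluation = evalm,
                 manifest = manifest, config = cfg))
}

decade_edges <- function(start_year, end_year) {
  e <- seq(as.integer(start_year), as.integer(end_year) - 1L, by = 10L)
  unique(c(e, as.integer(end_year) + 1L))
}

# CSV writer with stable formatting so identical inputs give identical bytes.
write_csv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]])) {
      df[[nm]] <- formatC(df[[nm]], digits = 10, format = "g")
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
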