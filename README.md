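# wheatclim

Agro-climatic analysis of warming impacts on rainfed winter (rabi) wheat,
for crop physiologists and agro-climatologists working with multi-decadal
daily weather and phenology records.

Warming shortens wheat's thermal-time clock: seasons accumulate growing
degree days (GDD) faster, anthesis and maturity arrive earlier, the
grain-filling window shrinks, and yield falls — and late sowing pushes the
heat-sensitive flowering window deeper into the spring warm-up. `wheatclim`
implements that full analysis chain as tested, reusable R functions:

- **Synthetic daily weather** with the statistical structure the analysis
  assumes — linear warming trend β (°C decade⁻¹), harmonic seasonality,
  AR(1) temperature noise, Markov-chain/gamma rainfall — with calibrated
  presets for two Pothwar-plateau stations (Islamabad, Chakwal).
- **Phase-aware GDD**: GDD = (Tmax + Tmin)/2 − T_base, clamped at the phase
  optimum, zeroed when Tmax exceeds the phase ceiling, under the wheat
  cardinal-temperature triplets 4/22.0/32.7 °C (vegetative), 9.5/21.0/31.0
  (anthesis→grain fill) and 9.2/20.7/35.4 (grain fill→maturity); plus
  heat-stress-day counting and thermal-time inversion (`days_to_reach`).
- **Sowing-date scenarios**: five standard sowings (15 Oct … 24 Nov),
  anthesis-date arithmetic with the inclusive (sowing day = 1) convention,
  flowering-window temperatures, the relative-rise statistic
  (T_k − T_1)/T_k × 100, stage-partitioned rainfall, and maund/PKR/USD
  revenue arithmetic.
- **Trend statistics**: survey-style descriptives (sample SD, adjusted
  skewness, excess kurtosis), polynomial regression
  Y = β₀ + β₁X + β₂X² + … + ε, decadal summaries, Pearson correlation
  matrices.
- **Sensitivity grids** over a documented surrogate yield model
  Y = Y₀(1 − λΔT)(1 + γ ln(C/C_ref)), with yield loss (% per °C) =
  (Y_amb − Y_{+1°C})/Y_amb × 100 and yield change (% per 100 ppm).
- **Evaluation metrics** for observed-vs-simulated pairs: R² (squared
  Pearson correlation), RMSE, MAE, signed bias, and the S = a + bO
  regression against the 1:1 line.
- A **pipeline driver** (`run_pipeline`) chaining everything into a
  byte-reproducible bundle of CSV/JSON outputs from a config + seed.

## Worked example

```r
library(wheatclim)

cfg <- list(site = "islamabad", start_year = 1980L, end_year = 2020L, seed = 1L,
            scenarios = list(yield_losses = c(0, 0, 9, 15, 27)))
res <- run_pipeline(cfg, "demo_out", quiet = TRUE)

res$scenarios$table[, c("label", "sowing", "anthesis", "window_tmean",
                        "relative_rise_pct", "yield_loss_pct")]
#>   label sowing anthesis window_tmean relative_rise_pct yield_loss_pct
#> 1 SD1   15-Oct 27-Jan           15.5              0                 0
#> 2 SD2   25-Oct 06-Feb           16.0              3.10              0
#> 3 SD3   04-Nov 16-Feb           17.2             10.0               9
#> 4 SD4   14-Nov 26-Feb           18.7             17.2              15
#> 5 SD5   24-Nov 08-Mar           20.5             24.5              27
```

Each row is one sowing date: delaying sowing from 15 October to 24 November
moves anthesis from late January to early March and raises the mean
temperature of the 10-day flowering window from 15.5 to 20.5 °C on this
synthetic climate — a 24.5 % relative rise — which is the mechanism behind
the supplied crop-model yield losses (last column). The published
flowering-window temperatures give the same statistic directly:

```r
relative_rise(11.06, 16.61)  # Islamabad, earliest vs latest sowing
#> [1] 33.41361
relative_rise(10.24, 15.92)  # Chakwal
#> [1] 35.67839
```

The same bundle carries the thermal-time phenology and its trends
(41 seasons at the preset's 0.40 °C decade⁻¹ warming):

```r
p <- res$phenology
c(mean_dta = mean(p$dta), mean_dtm = mean(p$dtm), mean_gdd = mean(p$total_gdd))
#>  mean_dta  mean_dtm  mean_gdd
#>  107.1463  136.1463 2137.2020

res$sensitivity$stats
#>   yield_loss_pct_per_degC yield_change_pct_per_100ppm
#> 1                    4.79                        1.25
```

Mean days to anthesis (~107) and maturity (~136) sit at the long-term
baselines the thermal targets were calibrated to; the sensitivity grid
(100 noisy replicates per cell here) recovers the surrogate's configured
4.5 % yield loss per °C to within Monte-Carlo error, alongside the modest
log-saturating CO₂ benefit.

`demo_out/` then contains `weather.csv` / `weather.wth`, `phenology.csv`,
`descriptive_stats.csv`, `trend_fits.json`, `correlation.csv`,
`scenario_table.csv`, `stage_rainfall.csv`, `sensitivity_cells.csv`,
`sensitivity_summary.json`, `eval_metrics.json` and a `manifest.json`;
re-running with the same config and seed reproduces every file
byte-for-byte.

See `vignettes/wheatclim-methods.Rmd` for the models, parameter
conventions, calibration choices and known limitations.

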