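---
title: "Methods: warming, thermal time and rainfed wheat in wheatclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: warming, thermal time and rainfed wheat in wheatclim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wheatclim)
```

## The problem

Rainfed (barani) winter wheat on the Pothwar plateau of northern Pakistan is
sown in mid-October and harvested by late April. Its two most heat-sensitive
windows — flowering (anthesis) and grain filling — fall in late winter and
spring, exactly when multi-decadal warming is strongest. Warmer seasons
accumulate thermal time faster, so anthesis and maturity arrive earlier, the
grain-filling window shrinks, and yield falls; delayed sowing pushes
flowering deeper into the spring warm-up and compounds the exposure.

`wheatclim` implements the complete analysis chain for studying this
mechanism over a multi-decadal daily weather record: a stochastic weather
generator standing in for station data, phase-aware growing-degree-day
(GDD) accumulation, sowing-date scenario tables, trend and correlation
statistics, a temperature x CO2 yield-sensitivity grid over a surrogate
yield model, and observed-versus-simulated evaluation metrics.

## The synthetic weather generator

Long station records of the kind this analysis needs are rarely
redistributable, so the generator is a first-class module, not a test
fixture. Daily mean temperature is

$$T(t) = \mu + \beta\,\frac{y(t)}{10} -
  A\cos\!\Big(\frac{2\pi\,(d(t)-d_0)}{365.25}\Big) + \varepsilon_t,
\qquad \varepsilon_t = \rho\,\varepsilon_{t-1} + \eta_t,$$

with `annual_mean_temp` $\mu$ (degC), linear warming trend $\beta$ (degC per
decade, applied to elapsed years $y(t)$), a single-harmonic seasonal cycle of
amplitude $A$ with minimum at day-of-year $d_0$ (default 10 January), and a
stationary AR(1) residual with lag-1 coefficient $\rho$ (default 0.7) and
stationary SD `residual_sd` (default 2 degC). Tmax and Tmin are split around
$T(t)$ by a sampled diurnal range (normal, floored at 0.1 degC so the range
stays positive). Rainfall occurrence follows a two-state Markov chain
(`p_wet_given_dry`, `p_wet_given_wet`) and wet-day amounts a gamma
distribution; rainfall is generated on an independent random substream of
the master seed, so switching rainfall parameters never perturbs the
temperature draws. Rainfall and temperature are statistically independent:
no cross-dependence structure is modelled.

A single cosine rather than a monthly lookup is the fewest-parameter shape
that reproduces a Pothwar-like winter season; richer harmonics would add
parameters the downstream statistics never see.

### Site presets and their calibration

`site_preset()` encodes the two study stations as emulation targets for the
growing-season (15 October - 30 April) climatology:

| preset | seasonal mean T | warming trend | mean seasonal rain |
|---|---|---|---|
| `islamabad` | 19.3 degC | 0.40 degC/decade | ~428 mm |
| `chakwal` | 18.3 degC | 0.25 degC/decade | ~297 mm |

The annual-mean parameter is solved numerically at preset construction so
that the noise-free seasonal mean of the midpoint season equals the target;
the preset tolerance (+/- 0.5 degC on 20-200 seed means) exceeds three
Monte-Carlo standard errors, so a calibration failure is a real defect, not
noise. The Chakwal warming rate is published ambiguously (about 1 degC per
decade in one place, about 1 degC over the whole 41 years in another); the
preset defaults to 0.25 degC/decade, the total-rise reading, and the trend
is an ordinary configuration field for anyone preferring the other reading.

Rainfall parameters (few wet spells, gamma shape 0.15 with a heavy scale)
are chosen so winter rain arrives in a handful of western-disturbance
events. This makes seasonal totals clearly right-skewed (skewness roughly
+0.8 to +1.5 across seeds), which is the qualitative structure the analysis
assumes. Two features of the real records are deliberately **not**
reproduced: the extreme published seasonal-rainfall skewness (~3.2-3.5,
driven by single outlier seasons such as a ~1950 mm year) and the published
interannual seasonal-temperature SD of ~2.2 degC — a 198-day mean of daily
AR(1) noise is necessarily much smoother (~0.35 degC). Tests calibrated on
the generator therefore demonstrate correctness of the *procedures*, not
agreement with the withheld station data.

## Growing degree days with cardinal temperatures

Daily thermal time is $\mathrm{GDD} = (T_{max}+T_{min})/2 - T_{base}$,
bounded by the phase's cardinal temperatures:

| phase | $T_{base}$ | $T_{opt}$ | $T_{ceil}$ |
|---|---|---|---|
| sowing to anthesis (vegetative) | 4.0 | 22.0 | 32.7 |
| anthesis to grain filling | 9.5 | 21.0 | 31.0 |
| grain filling to maturity | 9.2 | 20.7 | 35.4 |

The default response rule is the simplest one consistent with a linear GDD
formula plus a ceiling statement: the daily mean is clamped to
$[T_{base}, T_{opt}]$ before subtracting the base (so a day contributes at
most $T_{opt}-T_{base}$), and a day whose **Tmax** exceeds the phase ceiling
contributes zero. Tmax, not the mean, triggers the ceiling because terminal
heat stress in this literature is phrased against daily highs (days above
35 degC). A clearly-labelled trapezoidal mode (`method = "trapezoid"`)
declines linearly between optimum and ceiling instead, for users who prefer
a continuous response; it is never the default. Days with Tmax above 35 degC
are additionally counted as heat-stress days (`heat_zero_threshold`,
configurable), separate from the 35.4 degC grain-filling ceiling — the two
thresholds are deliberately distinct parameters because the source
conventions differ by 0.4 degC.

`days_to_reach()` inverts cumulative thermal time to a calendar day and
returns a flagged `NA` (not an error) when a season ends before the target:
non-attainment is an analysable outcome, not bad input.

All day counting is **inclusive** (sowing day = day 1): a 15 October sowing
reaching anthesis on 22 January has DTA 100. This convention reproduces all
five 100-day scenario rows and the 105-day first row exactly; the remaining
105-day rows in the published table are internally one day off under any
single convention, and a single documented convention was preferred over a
per-row fudge. Season windows are computed from the real Gregorian
calendar: 15 October - 30 April inclusive is 198 days over a non-leap
February (199 otherwise). The "196 days" figure sometimes quoted for this
window is kept only as documentation; no computation uses it.

## Sowing-date scenarios

The standard experiment evaluates five sowings (15 Oct, 25 Oct, 4 Nov,
14 Nov, 24 Nov) with days-to-anthesis fixed at the site's long-term mean
(105 days Islamabad, 100 Chakwal) and a 10-day flowering window. For each
scenario the window's mean temperature is the across-years average of the
10-day daily-mean window opening on the anthesis date. The headline
statistic is the relative rise of flowering temperature for sowing $k$
versus the earliest sowing,

$$\mathrm{rise}_k = \frac{T_k - T_1}{T_k}\times 100,$$

normalised by the **later** temperature — the only convention that
reproduces both published values (33.41 % and 35.67/35.68 %) from the
published window temperatures. Scenario tables are assembled in a non-leap
reference year, matching the published calendar arithmetic.

Stage-partitioned rainfall splits each season at the site's fixed DTA
(vegetative: days 1..DTA; reproductive: the rest of the window) — the split
conserves season totals exactly — and aggregates within decades. Whether
decadal cells are per-season means (default) or decade sums is a
configuration flag: the published decadal table is ambiguous on this point
(its vegetative-rainfall magnitudes are inconsistent with per-season
seasonal means), so no default is claimed to be "the" published convention.

The economics helper converts yield to 40-kg maunds and revenue at a fixed
support price (default 3100 PKR per 40 kg); the PKR-to-USD rate is an
explicit input because no single published rate is authoritative.

## The surrogate yield model and sensitivity statistics

Process-based crop-simulator output (DSSAT CSM-CERES-Wheat) is out of
scope; the sensitivity machinery instead runs over a transparent surrogate,

$$Y(\Delta T, C) = Y_0\,(1 - \lambda\,\Delta T)\,
  \Big(1 + \gamma\,\ln\frac{C}{C_{ref}}\Big) + \epsilon,$$

floored at zero: a linear fractional loss $\lambda$ per degC of warming,
a saturating (logarithmic) CO2 fertilisation response $\gamma$, and
optional Gaussian noise. This is the simplest shape consistent with a
near-linear %/degC loss and a saturating CO2 benefit; it is labelled a
surrogate everywhere and makes no claim to emulate crop-simulator dynamics.
Presets: Islamabad $Y_0 = 4.0$ t/ha, $\lambda = 0.045$ (4.5 %/degC);
Chakwal $\lambda = 0.06$ — both back-derived from paired percent/absolute
loss statements (4.5 % ~ 0.18 t/ha and 6 % ~ 0.24 t/ha imply a 4.0 t/ha
ambient baseline).

The sensitivity statistics are the standard pair: yield loss
$(Y_{amb}-Y_{+\Delta})/Y_{amb}\times 100$, averaged per degC across
increments, and yield change $(Y_{C+n}-Y_C)/Y_C\times 100$, scalable per
100 ppm. The CO2 reference defaults to 350 ppm (the level the change
formula is defined against) with 410 ppm — the other published baseline —
one argument away; the package takes no position on which the original
analysis used. The default grid spans $\Delta T$ = 0..8 degC and CO2
350..800 ppm.

## Evaluation metrics

`evaluate_pairs()` reports the crop-model validation set: $R^2$ as the
squared Pearson correlation of observed and simulated (the printed-formula
definition; the $1-\mathrm{SSE}/\mathrm{SST}$ form is also returned as
`r_squared_model` because the two diverge under bias), RMSE, MAE, signed
bias (mean of simulated minus observed; positive = over-simulation), and
the slope/intercept of $S = a + bO$ read against the 1:1 line. The suite
asserts the defining identities (RMSE >= MAE >= 0, RMSE >= |bias|, swap
antisymmetry of bias, $\mathrm{RMSE}^2 = \mathrm{bias}^2 +
\mathrm{var}_{pop}(S-O)$) — note that published validation panels
occasionally print MAE > RMSE, which these identities show to be
impossible; the package flags rather than emulates such values.

## Descriptive and trend statistics

`describe()` produces the eight survey-style columns (range, min, max,
mean, SD, variance, skewness, kurtosis) with sample (n-1) denominators,
adjusted Fisher-Pearson skewness and **excess** kurtosis (type-2
estimators) — the convention under which published negative kurtosis values
are possible. Polynomial trends (`fit_polynomial()`) default to degree 2,
the degree used throughout decadal agro-climatic regressions, with raw
polynomial basis, $R^2$ against the mean model and the overall-F p-value
(reported, never used for automated decisions). `pearson_matrix()` and
`decadal_summary()` round out the module; empty decades are flagged rows,
never silently dropped.

## The pipeline and its phenology stage

`run_pipeline()` chains weather -> phenology -> trends -> scenarios ->
sensitivity -> evaluation into one bundle of plain CSV/JSON files plus a
manifest (config, its MD5, seed, package version). Outputs are
byte-reproducible from config + seed; nothing in the bundle depends on run
time or environment.

The phenology stage derives each season's DTA and DTM by thermal-time
inversion: DTA is the day vegetative-phase GDD reaches `anthesis_gdd`
(default 1340 degree-days), DTM the day the full three-phase accumulation
reaches `maturity_gdd` (default 1550). The defaults were calibrated once
against the Islamabad preset so the long-term means land near the
published baselines (DTA ~105, DTM ~135 days); they are per-site knobs, not
constants of nature. Grain yield in this stage is a transparent linear
response to the seasonal mean-temperature anomaly through the surrogate
loss rate — enough coupling for the trend and correlation machinery to have
signal, with no pretence of simulating crop growth.

One subtlety the tests document: uniform warming does *not* monotonically
shorten every season's DTA, because a +2 degC shift can push October days
over the 32.7 degC vegetative ceiling and zero their thermal time; the
mean DTA still falls. The strict monotonicity property holds only while no
day crosses a ceiling, and is asserted under exactly that guard.

## Problem sizes and numerical choices

The shipped test and verification sizes are chosen to make Monte-Carlo
error negligible relative to each assertion: trend recovery uses 200
independent 41-season series (the across-seed mean slope has standard error
~0.003 degC/decade); preset climatology checks use 20-seed means against a
+/- 0.5 degC band; noisy grid recovery uses 500 replicates per cell against
a 3-standard-error band; the GDD oracle sweeps 100 random 30-day series at
1e-9 tolerance; metric oracles use 25-30 random vectors at 1e-10. AR(1)
innovations are scaled by $\sqrt{1-\rho^2}$ so `residual_sd` is the
stationary SD, and the recursion is initialised from the stationary
distribution — no burn-in is needed. Ties in `days_to_reach()` resolve to
the earliest qualifying day. Degenerate inputs (zero variance, reversed
intervals, gaps in strict mode, constant observed vectors) are errors that
name the offending quantity; gap-tolerant and flagged modes exist where a
practitioner would want to push through imperfect records.

## Known limitations

- The generator reproduces seasonal means, trend, positive rainfall skew
  and daily autocorrelation — not extreme-season rainfall outliers, the
  full interannual temperature variance, temperature-rainfall dependence,
  or solar radiation (written as a missing-value placeholder in station
  files).
- The surrogate yield model is a response surface for exercising the
  sensitivity statistics; its numbers say nothing about any particular
  cultivar or soil.
- Published regression coefficients and validation statistics that depend
  on the withheld 41-year station record are out of reach by construction;
  the package reproduces procedures and the self-contained worked values
  only.
- Vernalisation and photoperiod are not modelled.
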