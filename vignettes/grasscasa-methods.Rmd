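---
title: "Methods: a modified CASA NPP model with climate attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a modified CASA NPP model with climate attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grasscasa)
```

## The model

`grasscasa` implements a light-use-efficiency (CASA-family) model of
monthly net primary productivity for semi-arid grassland, plus the
statistical machinery used around such models: station-to-raster
interpolation, plot-level validation, and pixel-wise correlation /
partial-correlation attribution of NPP to precipitation and temperature.

Monthly NPP is `APAR × ε`. APAR is incident total solar radiation times
the PAR fraction (0.5) times FPAR, the fraction of PAR absorbed by the
canopy. FPAR is estimated twice — linearly in NDVI and linearly in the
simple ratio `SR = (1+NDVI)/(1−NDVI)` — and the two estimates averaged.
Both rescalings send per-class calibration bounds (the 5th and 95th
percentiles of the class's NDVI history) to the global FPAR limits 0.001
and 0.95, and both clamp rather than error outside the bounds:
remote-sensing reflectance is noisy and occasional out-of-range NDVI is
expected, not exceptional.

Efficiency is `ε = Tε1 × Tε2 × Wε × ε_max`, with `ε_max` = 0.542
gC·MJ⁻¹ (grassland) and 0.429 gC·MJ⁻¹ (shrub). The stress scalars:

* `Tε1 = 0.8 + 0.02·T_opt − 0.0005·T_opt²` penalises pixels whose
  optimum growth temperature is extreme; it is zeroed in months whose
  mean temperature is ≤ −10 °C and floored at 0.
* `Tε2` is a double logistic in the departure of the monthly mean from
  the pixel optimum (peak ≈ 1.1814/(1+e^(−2))/(1+e^(−3)) ≈ 0.92 near the
  optimum), falling faster on the warm side (slope 0.3 vs 0.2). Once a
  month runs more than 10 °C above the optimum, the scalar is capped at
  its value at the optimum, so hot months can never appear less stressed
  than the optimum itself.
* `Wε = 0.5 + 0.5·EET/PET` spans [0.5, 1]: production is halved, not
  eliminated, under complete drought. PET is Thornthwaite's monthly
  formulation (annual heat index, day-length and month-length
  corrected); EET comes from a single-layer soil-moisture bucket —
  monthly evapotranspiration is the smaller of demand and
  precipitation-plus-store, with the store capped at a configurable
  capacity. `PET = 0` (a frozen month) is treated as the driest limit.

`T_opt` is defined per pixel and year as the mean temperature of the
month with that year's maximum NDVI — the month the canopy itself
"chose". December–February NPP is forced to zero everywhere: under snow
cover and dormancy the model's annual total is growing-season NPP, and
the annual sum then exactly equals spring + summer + autumn
(meteorological seasons, Mar–May / Jun–Aug / Sep–Nov; the calendar
boundaries are configurable since season definitions vary between
agencies).

## Choices where the method family is genuinely open

* **Interpolation.** Sparse national station networks are commonly
  gridded either by kriging or by inverse-distance weighting; with nine
  stations a variogram cannot be estimated stably, so the package uses
  IDW (power 2, configurable) on pixel centres. A pixel whose centre
  coincides with a station reproduces the station value exactly, and the
  positive-weight formulation guarantees the maximum principle (output
  bounded by station extremes).
* **Sunshine to radiation.** Station archives record sunshine duration,
  not radiation. The Ångström–Prescott relation with the FAO default
  coefficients a = 0.25, b = 0.50 converts monthly sunshine fraction
  `n/N` to total radiation, with `Ra` and `N` from standard solar
  geometry summed daily over the month. Recorded `n` occasionally
  exceeds the astronomical maximum; the ratio is clipped at 1 (with a
  warning beyond floating-point excess).
* **SR calibration bounds.** The SR bounds are the simple ratio
  *evaluated at* the class NDVI percentiles rather than percentiles of
  SR itself. Because SR is strictly monotone in NDVI the two definitions
  coincide for continuous distributions; evaluating at the NDVI
  percentiles keeps the two FPAR branches consistent by construction.
* **Evapotranspiration sub-model.** Regional ET models differ widely;
  the package uses the smallest testable formulation (Thornthwaite +
  bucket, capacity 100 mm, initialised half full). The bucket is run
  through the whole record in time order so early-season moisture
  carries over; the initialisation matters only for the first spring.
* **Bias sign.** Validation reports `bias = mean(observed − estimated)`,
  so a *negative* bias means the model runs high. The regression is of
  estimated (y) on observed (x).
* **County attribution.** County series are built by averaging NPP and
  climate over the county's (vegetated) pixels first and correlating the
  county-mean series, not by averaging pixel-level coefficients. The two
  orders differ; the county-mean order matches how agency statistics are
  tabulated.
* **Significance.** Per-pixel p-values are two-tailed t tests,
  `t = r·√((n−k)/(1−r²))`, k = 2 for plain and 3 for partial
  correlation, deliberately uncorrected across pixels (maps of
  uncorrected significance are the field's convention); a
  Benjamini–Hochberg option exists but is off by default. With a 13-year
  record the per-pixel power is low — every map carries `n_years` so
  consumers can judge.

## The synthetic world

`make_world()` generates the complete, coupled input set: red/NIR
reflectance, land cover (grassland with scattered shrub and barren
pixels), monthly records for a nine-station network, a 3×3 county
partition, clip-plot biomass observations and county livestock series.
Defaults emulate the study conditions: 13 years, 295 mm mean annual
precipitation with ~59% falling in July–September, 3.36 °C mean annual
temperature with a continental seasonal cycle, and a west→east moisture
gradient (+50% across the grid) that productivity follows.

Construction, per pixel `p` and year `y`:

* annual precipitation `P = base(p) · f(y)`: a linear west→east ramp
  times static lognormal-like pixel noise (SD 0.10), times a region-wide
  lognormal yearly factor (SD 0.20, matching interannual swings of
  roughly ±30–60%);
* yearly temperature anomalies (SD 0.9 °C) are drawn correlated with the
  log precipitation factor (default ρ = −0.3: wet years run cool);
* latent annual productivity
  `A = 0.8 gC·m⁻²·mm⁻¹ · base(p) · (1 + g_P·dP) · (1 + g_T·dT) + noise`,
  with `dP` the fractional precipitation anomaly and `dT` the
  temperature anomaly. The default gains are `g_P = 0.8` and `g_T = 0`
  (temperature acts only through its correlation with precipitation),
  and 0.8 gC·m⁻²·mm⁻¹ puts the regional mean near 240 gC·m⁻²·yr⁻¹, the
  right order for semi-arid steppe;
* monthly latent productivity spreads `A` over a fixed growing-season
  template (zero December–February, peak in July); NDVI is proportional
  to monthly latent productivity (scaled to peak at 0.85, barren pixels
  fixed at 0.05), and reflectance is back-solved with red fixed at 0.08
  so that `NDVI = (NIR−red)/(NIR+red)` holds to machine precision.

Two details exist purely so that stated invariants are exact rather than
asymptotic. First, multiplicative pixel noise (static and yearly) is
centred within each column over vegetated pixels, so vegetated
column-mean productivity follows the configured gradient exactly — the
west→east monotonicity is a property of every realisation, not just of
the expectation. Second, interannual anomalies are region-wide, so the
anomaly series a station samples is the same one the latent coupling
uses; a noiseless world therefore has pixel productivity exactly
collinear with precipitation (r = 1), which also means the temperature
partial correlation is there *undefined* (the control absorbs all
variance) — the implementation returns nodata for controls within
1e−12 of |r| = 1, and sign-neutrality of the temperature partial is
checked on low-noise worlds instead.

What the generator does **not** emulate: sensor physics and atmospheric
effects (no cloud contamination, no compositing artefacts — the
maximum-value compositor is exercised on constructed fixtures instead),
spatially structured storm tracks (yearly anomalies are regionally
uniform), landscape pattern in land cover, soil heterogeneity, grazing
feedbacks on NDVI, and real station geometry. Passing tests therefore
demonstrate that the pipeline's machinery is correct and recovers known
couplings under realistic magnitudes; they say nothing about how well
CASA's structural assumptions fit any particular real grassland.

## Numerical conventions

* Rasters are row 1 = north, pixel-centre coordinates, 0-based maths on
  1-based R indices; nodata is `NA` in memory and a sentinel (−9999) on
  disk (ESRI ASCII grid, 15 significant digits, which round-trips
  doubles for all practical purposes). Nodata never enters statistics.
* NDVI with `NIR + red = 0`, SR at NDVI = 1, correlation of a
  zero-variance series, and partial correlation with a collinear control
  all yield nodata rather than errors; degenerate *configurations*
  (empty seasons, < 3 validation pairs, constant observed values,
  missing months, grid mismatches) are hard errors that name the
  offending input.
* Ties in the month-of-maximum-NDVI rule resolve to the earliest month.
* Calibration requires ≥ 20 valid NDVI samples per class and strictly
  separated percentiles; a constant NDVI history is a hard error.
* A 365-day year is used in solar geometry and month lengths (no leap
  days): the model operates on monthly climatologies where a single day
  is far below the noise floor.
* Pipeline stages write to a temporary directory renamed into place on
  success, so a failed stage leaves no partial outputs; reruns with the
  same configuration are byte-identical.

## Test design

The suite checks each operation against an independent oracle (closed
forms for OLS/RMSE and the partial-correlation/residual-regression
identity; a daily-loop solar-geometry oracle; brute-force IDW sums), and
the assembled model against a per-pixel scalar recomposition of the
exported primitives. Test worlds are kept small — 8×8 to 20×20 pixels
and 3 to 13 years for unit tests, one 50×50, 13-year world for the
attribution sign-recovery property — sizes at which every property
tested is already exact or statistically stable, and a full run of the
suite stays under a minute.

## Known limitations

* One-at-a-time first-order partial correlations only; no lagged
  responses, no multivariate controls, no spatial-autocorrelation
  correction of significance.
* The ET sub-model is intentionally minimal; swapping in a calibrated
  regional ET model would change `Wε` levels (though much less its
  interannual signal).
* ε_max values are literature constants per class, not fitted here.
* IDW with nine stations cannot resolve sub-station-scale precipitation
  features; attribution results at pixel scale inherit the smoothness of
  the interpolated fields.
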