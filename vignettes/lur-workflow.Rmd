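---
title: "Land use regression exposure modelling with lurtools: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land use regression exposure modelling with lurtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lurtools)
```

## The problem and the model

Passive-sampler campaigns measure a pollutant (here NO~2~ and PM~2.5~, in
µg/m³) for one week at a time at up to ten sites simultaneously, twice per
site (once per season). Land use regression (LUR) turns those sparse
measurements into a continuous exposure surface by regressing site
concentrations on geographic predictors computed around each site:

$$ y_i = \beta_0 + \sum_j \beta_j x_{ij} + \varepsilon_i $$

where each $x_{ij}$ is a buffer aggregate (count of point sources, clipped
road length, clipped land-use area, mean vegetation index) or an inverse
distance to the nearest feature. Because sites are measured in different
weeks, raw values confound space with weather; a continuously operating
reference monitor supplies the temporal correction. The package implements
the whole chain — synthetic study generation, GIS feature engineering,
temporal adjustment, supervised selection, validation, and surface
prediction — with no external data dependency.

## The synthetic study world

`study_config()` states one fixed world; the defaults are the conditions a
field campaign of this kind reports, and they are not revisited per test:

* **Region**: 4 km × 3 km, local planar Cartesian metres. Buffers in this
  literature are metric; geodesy is orthogonal to the method and omitted.
* **Sites**: 95, stratified 60/30/10 into near (< 50 m), intermediate
  (50–100 m) and background (> 100 m) distance to a major road, via
  largest-remainder quotas and rejection sampling (57/29/9 at n = 95).
* **Seasons**: warm 2015-11-02..2016-03-27, cold 2016-06-06..2016-09-25;
  at most 10 sites measured per calendar week; one week per site and
  season.
* **Reference station**: hourly PM₁₀ around seasonal means 24.9 (warm) and
  28.9 (cold) µg/m³ with AR(1) day-to-day deviations (φ = 0.7) and hourly
  noise; solar radiation as a 06:00–18:00 half-sine with a per-day cloud
  factor; NO₂ as the linear function 17.35 + 1.0·PM₁₀ − 0.07·solar plus
  noise. That linear form is applied at the hourly level for simplicity, so
  noon NO₂ can dip negative at low PM₁₀ — daily means, the working
  resolution of the adjustment, stay positive. 2% of hours are blanked at
  random and NO₂ is blanked entirely after 2016-01-15, mimicking a monitor
  decommissioned mid-study.
* **Exposure truth**: intercept 18 µg/m³ plus three active predictors
  (major-road length in 300 m, grills in 1000 m, NDVI mean in 500 m with a
  negative sign) and a ±4 µg/m³ seasonal offset; means clamp at 0.
* **Measurement error**: `noise_sd = 2` µg/m³ iid per weekly record. No
  published value exists for the sampler error; this is a free parameter
  chosen once as a plausible magnitude, and tests that need exactness set
  it to zero instead of relying on it.
* **Losses**: 4% of records dropped uniformly at random (losses are
  reported in such campaigns without structure).

Every stochastic layer draws from its own RNG substream keyed by
`(master seed, layer name)` — adding a layer never perturbs another — and
each record stores its additive decomposition (true mean + regional
deviation + noise draw), so downstream recovery is checkable exactly.

Weekly measurement values are built as *site truth + reference deviation +
noise*, where the deviation is computed from the generated reference
station's **daily** series — the same resolution the adjuster uses. This
is precisely the parallel-series assumption under which a differential
correction factor is unbiased, and it makes the closed-form recovery test
(acceptance criterion 2) exact rather than approximate.

What the generator does **not** emulate: realistic road-network topology,
dispersion physics and wind, spatially structured sampler loss, transient
sources that appear and vanish between seasons, and real projections. A
green recovery test therefore establishes that the *pipeline arithmetic*
is right under its stated assumptions, not that the method would attain
any particular R² on real data.

## Geometry conventions

All predictor extraction is exact planar geometry, not rasterized
approximation (25 m buffers make approximation error material):

* Buffers are **closed** discs; a feature exactly on the boundary counts
  as inside (a deterministic, documented tie rule — whether boundary
  features were counted in the original campaigns is unstated).
* Polyline clipping solves the segment–circle quadratic; polygon clipping
  uses the Green's-theorem decomposition (triangle terms inside the disc,
  circular-sector terms outside), exact for simple rings of either
  orientation.
* Raster membership is by cell centre in the disc — standard for 30 m
  cells against ≥ 30 m radii.
* Inverse distance and inverse squared distance floor the distance at 1 m:
  homes can abut roads, and the division-by-zero case is otherwise
  undefined. The same floor keeps Moran's weights finite for coincident
  sites.
* Canonical radius sets are enforced on predictor specs (25/50/100/300/
  500/1000 m for vector layers, 30/100/150/200/500/750 m for raster
  means) unless explicitly relaxed.

## Temporal adjustment

* A daily mean is computed when **strictly more than 25%** of the 24
  hourly slots are present (7+ of 24); the boundary reading is literal and
  the threshold is configurable (`min_frac`).
* Failing days take the mean of the nearest previous and next qualifying
  daily values; at the series ends the fill is one-sided (the unstated
  edge case, declared here as a convention).
* PM₂.₅ is estimated as 0.5 × PM₁₀ daily means.
* NO₂ gaps are filled from an OLS of NO₂ on PM₁₀ and solar radiation
  fitted on the overlap (`fit_gap_fill()`, ≥ 30 days required); the
  published station-specific coefficients (17.35, 1.0, −0.07; r = 0.82)
  ship as `gap_fill_preset()` for reproduction runs but are **not** the
  default, because they belong to one particular monitor. The preset's
  PM₁₀ coefficient is taken as exactly 1.0 as printed.
* The correction factor is (reference week mean − reference season mean),
  computed from daily means and subtracted from the measurement; negative
  results clamp to exactly 0 with a flag. Clamping only ever raises a
  value.
* Within-season repeats are averaged first; the annual mean is the
  unweighted mean of the available seasonal means, so a season with more
  repeats cannot dominate. (The alternative — adjusting each record to the
  annual reference mean — differs only when season lengths are unequal;
  the season-first structure mirrors the campaign design.)

## Supervised forward selection

Candidates must be non-zero for strictly more than 10% of sites
("non-null" read as non-zero: buffer predictors have structural zeros, not
missingness); constant columns are dropped unconditionally. Selection then
proceeds from the intercept-only model: every remaining candidate is fit,
a candidate is eligible only if its own coefficient carries its a-priori
sign **and** no previously accepted term flips sign, and the best eligible
gain enters if it is ≥ 1 percentage point of R². Ties break
lexicographically by predictor name, making the procedure a total,
deterministic order; the full trace (gains, veto reasons) is retained in
the fit object.

* R² in the 1% rule is the **plain** coefficient of determination;
  `adjusted_r2 = TRUE` switches the whole procedure to adjusted R² for
  ESCAPE-manual fidelity.
* Pruning order is VIF (≥ 3 dropped, worst first) before p-value (≥ 0.1
  dropped, worst first), refitting after each drop: collinearity distorts
  p-values, so it is resolved first.
* Cook's distance ≥ 1 **flags** sites and records the maximum; it never
  auto-removes an observation — removal is an analyst action.
* No minimum sites-per-term rule is imposed; a warning is logged when the
  model exceeds n/10 terms.
* A predictor family may enter at several radii (as published models do);
  a note is emitted when nested radii of the same source co-occur.
* An empty candidate set or an all-vetoed first round returns the
  intercept-only fit — a valid outcome, not an error.

## Validation

* LOOCV refits **coefficients only** on each n−1 subset; the term set is
  frozen (re-running selection per fold would validate a different model
  at every fold).
* Validation R² is the squared Pearson correlation of observed and
  predicted (the field's convention when no formula is printed);
  `r2_method = "ss"` gives 1 − SSE/SST.
* Moran's I uses row-standardized inverse-distance weights with the 1 m
  floor and a two-sided permutation p-value,
  p = min(1, 2·min(p_lo, p_hi)) with add-one correction, 999 permutations
  by default; the smallest attainable p is 2/(B+1). Both the weight matrix
  and the inference scheme are package choices (the originals are
  unstated) and are configurable.
* RMSE and NMB follow their standard definitions; NMB is undefined (NA,
  not an error) when observations sum to zero.

## Exposure surfaces

Receptor predictions rebuild the fit's term columns with the same
geometric operations used at training sites — never by interpolating a
previously computed grid — and clamp negatives to 0 (physical floor; no
upper truncation). The default grid cell is 25 m, the smallest vector
buffer; grids export as ESRI ASCII plus a rendered image.

## The recovery experiment (acceptance criterion 4)

The parameter-recovery study fixes, a priori: three active predictors with
standardized effects of exactly 0.8 (comfortably above the stated 0.5
floor for every realization, because the coefficients are constructed on
the standardized scale), noise calibrated so the latent R² is exactly 0.8
for the realized design, and twelve noise candidates drawn from generator
categories that are independent of the active sources. Candidates that
physically contain an active source (the all-roads layer contains the
major roads; a second radius of the same smooth NDVI field correlates
above 0.9) are deliberately not presented as "noise": supervised forward
selection is not claimed to disambiguate near-collinear proxies of one
underlying source, and treating a proxy swap as a recovery failure would
test a property the method does not promise. With that stated world, all
three actives are recovered in ≥ 90% of seeded runs, at most one noise
term enters in ≥ 80%, and the coefficient RMSE shrinks monotonically over
n ∈ {50, 95, 500}.

## Numerical choices

* Gain comparisons use a 1e-12 slack on the 1% threshold; sign checks are
  exact on the OLS coefficient.
* Exact-recovery assertions (temporal closed form, surface reproduction)
  run at noise 0 and tolerate 1e-9/1e-6 respectively; geometry oracles
  allow 0.5% on densified lengths and 1e-9 on distances.
* Degenerate inputs are typed errors, not NAs: empty layers (distinct
  from a zero distance), rank-deficient gap-fill or LOOCV designs,
  zero-variance residuals, buffers leaving the raster extent (naming the
  site), weeks outside their season window.
* Seeds: every stochastic step derives a 31-bit substream seed from the
  master seed and a label; permutation tests take an explicit seed.

## Command-line pipeline

`exec/lur` (or `lur_cli()`) exposes
`simulate | extract | adjust | fit | validate | predict`, each reading one
JSON config plus `--log-level`. Keys (all optional; defaults in
parentheses): **simulate** — `seed` (1), `n_sites` (95), `area_width`
(4000), `area_height` (3000), `weekly_capacity` (10), `noise_sd` (2),
`ref_gap_fraction` (0.02), `lost_fraction` (0.04), `no2_cutover`,
`season_windows`, `out_dir` ("study"); **extract** — `study_dir`,
`distance_floor` (1), `out_csv`; **adjust** — `study_dir`, `min_frac`
(0.25), `gap_fill` ("fit" or "preset"), `out_csv`; **fit** —
`matrix_csv`, `adjusted_csv`, `pollutant` ("no2"), `season` ("annual"),
`screen_threshold` (0.10), `min_gain` (0.01), `max_vif` (3), `max_p`
(0.1), `adjusted_r2` (false), `out_json`; **validate** — `fit_json`,
`matrix_csv`, `adjusted_csv`, `study_dir`/`sites_csv`, `n_permutations`
(999), `seed` (1), `out_json`, `pairs_csv`, `scatter_png`; **predict** —
`fit_json`, `study_dir`, `cell_size` (25), `bbox`, `receptors_csv`,
`out_asc`, `out_png`, `out_csv`. Thresholds default to the canonical
values everywhere.

## Known limitations

* The land-use tiling and gridded road network are caricatures; predictor
  collinearity structure in real cities (e.g. roads tracking commercial
  zoning) is absent, so selection behaviour here is a best case.
* PM₂.₅ truth shares the NO₂ spatial surface in the default world; the
  low spatial variability that depresses PM₂.₅ model performance in the
  field is not reproduced.
* The differential (subtractive) correction factor is the only adjustment
  offered; ratio-based adjustment is out of scope.
* Moran's I inference assumes exchangeable residuals under the null;
  heteroscedastic exposure errors would require a different null.
* A worked end-to-end example with concrete printed numbers lives in the
  README; every number there is produced by `scripts/acceptance.R`.
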