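---
title: "Modelling walking access to rural primary care: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling walking access to rural primary care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkaccess)
```

## The problem

In rural districts of low-income countries, essentially all travel to
health facilities happens on foot over footpath networks that rarely appear
in standard road databases. Accessibility estimates built from Euclidean
distance at an assumed constant speed, or from coarse friction surfaces,
can misstate door-to-facility travel time by tens of minutes per trip.
`walkaccess` implements the alternative: route every household over the
actual footpath graph to its nearest primary health care centre (PHC) and
nearest community health site (CHS), then convert route distance to time
with a walking-speed model calibrated on GPS field tracks.

Because the original field data (OpenStreetMap extracts, GPS recordings)
have no deposited accession, the package ships a first-class synthetic
district generator whose outputs have the statistical structure the
analysis assumes. Every stage is therefore testable end to end without any
download, and simulated-then-refitted parameter recovery is the package's
strongest correctness evidence.

## The travel-speed model

The response is the walking speed of a 10 s GPS point pair,
$v_{ij}$ (km/h) for pair $j$ of track $i$:

$$
v_{ij} = \beta_0 + f(|s_{ij}|) + \beta_r \frac{r_i}{10} +
\beta_d \mathbf{1}[d_{ij} > 13\,\mathrm{km}] + \beta_{L[ij]} +
\beta_{I[i]} + b_i + \varepsilon_{ij},
$$

with $s$ the signed slope (%) of the containing 100 m segment (the smooth
uses $|s|$: climbing and descending both slow walkers), $r_i$ the track's
daily rainfall (mm), $d$ the cumulative distance walked since the journey
origin (fatigue sets in past 13 km), $\beta_L$ land-cover effects relative
to the `mixed` reference, $\beta_I$ walker-class effects relative to
community staff, $b_i \sim N(0, \sigma_b^2)$ a per-track random intercept,
and $\varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2)$.

`published_model()` packages the reported coefficient set (intercept
3.27 km/h; rainfall −0.06 per 10 mm; long-distance −0.38; water −1.32,
forest +0.01, rice field −0.46, savanna −0.05, residential −0.52;
research team +1.20, local population +1.29). Evaluation is strictly
additive above a floor of 0.1 km/h, which prevents the algebra from
producing non-positive speeds on extreme slopes.

```{r}
m <- published_model()
predict_speed(m)                              # reference covariates
predict_speed(m, landcover_label = "water")   # 3.27 - 1.32
predict_speed(m, rainfall_mm = 20)            # 3.27 - 2 * 0.06
```

### The slope smooth

The source analysis reports the slope term only as a fitted non-linear
smooth with "an exponential decrease of speed at higher absolute values of
slope"; the curve itself is not published. The packaged default is the
parametric family $f(|s|) = -a\,(e^{b|s|} - 1)$ with $a = 0.1$ km/h and
$b = 0.05$ per percent, which matches that qualitative description, is
zero on flat ground by construction, and has two interpretable knobs. The
fitter can either re-estimate $(a, b)$ (profiling $b$ by 1-D
optimisation; $a$ enters linearly) or switch to a cubic B-spline in $|s|$
(`smooth = "bspline"`, default 8 df, basis constrained to vanish at 0,
optional ridge penalty). Both families are serialisable to the model JSON.

### Fitting: backfitting with an exact GLS inner step

`fit_speed_model()` alternates (i) estimation of all fixed effects plus
the smooth, (ii) BLUP shrinkage of per-track mean residuals
$\hat b_i = \frac{n_i \sigma_b^2}{n_i \sigma_b^2 + \sigma_\varepsilon^2}
\bar r_i$, and (iii) one-way-ANOVA moment updates of
$(\sigma_b^2, \sigma_\varepsilon^2)$. One design point deserves a note: a
literal Gauss–Seidel sweep (plain OLS on $y - \hat b$) converges at rate
$\approx 1 - \sigma_\varepsilon^2 / (\sigma_\varepsilon^2 + n_i\sigma_b^2)$
per iteration, which with the ~2,000 observations a long track contributes
is numerically stalled — intermediate coefficients are badly biased for
hundreds of iterations. Step (i) therefore solves the random-intercept GLS
*exactly* via the standard partial within-track demeaning transform
(weights $\lambda_i = 1 - \sqrt{\sigma_\varepsilon^2 /
(\sigma_\varepsilon^2 + n_i \sigma_b^2)}$). This is the same fixed point,
reached in about four passes. Wald standard errors come from the final
transformed regression; the marginal Gaussian likelihood gives AIC for
term-deletion comparisons.

The variance share "explained by the random effects" is defined as
$\sigma_b^2 / (\sigma_b^2 + \sigma_\varepsilon^2)$ — the source does not
state its exact definition, so this choice is documented and tested only
against the package's own generator.

### Variance-component calibration

Only the share (39.45%) is reported, not the component SDs. The generator
uses $\sigma_\varepsilon = 0.8$ km/h — a realistic 10 s GPS point-pair
residual scale — and derives $\sigma_b = 0.8\sqrt{0.3945/0.6055} \approx
0.646$ km/h so the share is exact. Recovery targets concern the share and
the coefficients, not the absolute SDs.

## The synthetic district

`district_config()` states the world once: a 10 × 10 km square at 25 m
raster resolution, 40 residential clusters averaging 14 buildings (every
cluster keeps the 4 buildings that define a residential area), 3 PHC and
12 CHS placed at mutually spread cluster centres, 500 m of terrain
relief, a savanna-dominated land-cover mix (55% savanna, 22% forest, 10%
rice field, 7% residential, 3% water, 3% other), and a 47.5 mm/day
rainfall ceiling — the largest daily rainfall observed during fieldwork.

* **Terrain** is Gaussian-filtered white noise rescaled to the configured
  relief (correlation length ~1/20 of the side), deterministic per seed.
* **Land cover** is allocated by sequential exact-count assignment against
  smooth random score fields: residential cells hug cluster centres, water
  and rice fields prefer valley floors, and each class receives its target
  cell count exactly up to rounding, so realized fractions are tight while
  patches stay contiguous. `mixed` is *not* a raster class; it only exists
  as a segment label. Cells of class `other` have no speed-model term, so
  a segment dominated by `other` falls back to the `mixed` reference.
* **The footpath network** is a Euclidean MST over cluster centres
  (guaranteeing connectivity) augmented with 3-nearest-neighbour links;
  edges are jittered polylines, so arc length exceeds the chord as real
  footpaths do.
* **GPS tracks** walk non-backtracking random walks over the junction
  graph, truncated at lognormal target lengths rescaled so 168 tracks
  total 871 km (capped at 22.9 km, the fitted range). Each 10 s step draws
  `max(floor, eta_segment + b_i + eps)`, where `eta_segment` is the
  fixed-effect predictor of the 100 m segment containing the *midpoint*
  of the step — the same rule used when tracks are read back, so
  generator and measurement agree on covariates up to boundary effects.

### The point-dropout calibration

Two published totals constrain the generator jointly: 871 km of tracks
and 57,719 point pairs at a 10 s cadence. Taken literally they imply a
mean pair speed of 5.4 km/h — faster than any plausible mean of the
published model itself (~3.5 km/h once walker premiums, slopes and land
cover are averaged). The only mechanism that reconciles the two numbers
under a strict 10 s protocol is lost GPS fixes: a dropped point turns two
10 s pairs into one 20 s pair, which the elapsed-time filter later
discards while the kilometres still count. The generator therefore drops
each emitted point with probability 0.2, calibrated once from
$q^2 = 57{,}719 / 89{,}000$ (the raw pair count implied by 871 km at the
model's mean speed) before any acceptance measurement was made. The
20-replicate mean retained pair count is ~57,000.

What a green test does *not* establish: the generator emulates the
statistical structure (additive effects, track heterogeneity, covariate
mixes along routes), not real Ifanadiana geography, hydrology, census
weights, or satellite-classification error. District-level results of the
original study (its Tables 1, 2, 4, 5) are not reproduction targets.

## Segmentation rules

Routes and tracks are split into 100 m segments (the last takes the
remainder). Slope is signed percent along the direction of travel from
bilinearly interpolated endpoint elevations. The land-cover label samples
the segment at ≥20 midpoint-spaced stations and takes the class covering
the largest share, or `mixed` below 50%. Pair observations map to the
segment containing the pair midpoint; the default filters drop pairs with
elapsed time outside 10 ± 2 s, implied speed above 10.8 km/h (3 m/s —
a GPS glitch, not walking), or coincident fixes, and the drop counts are
reported.

One boundary rule is worth stating: the cumulative-distance category of a
segment is decided by its *midpoint* against the 13 km threshold. The
written category bound "[0, 13] km" and the worked travel-time arithmetic
(a 14 km flat route spending exactly 13 km in the short category) are
only simultaneously satisfiable under the midpoint rule, which this
package adopts throughout (generator, fitter, predictor).

## Travel time and scenarios

`predict_route_time()` accumulates `length / speed` over a route's
segments, with cumulative distance measured from the route origin (the
household door) and rainfall scenario-constant along the route — daily
rainfall grids are far coarser than any route. `scenario_times()` reports
the dry (0 mm) and maximum-rainfall (47.5 mm) bounds one-way, without
doubling for return trips. Population predictions default to the
reference walker class (community staff), i.e. they carry no walker
premium; this choice is exposed as an argument because the source does
not state which class its population predictions used.

## Comparator methods

* **Euclidean**: straight-line distance at a constant 5 km/h.
* **Friction surface**: Dijkstra over the 8-connected raster cell graph;
  a step costs `length / (base_speed × slope_factor)`, base speeds come
  from a per-class table with network cells burned in at path speed, and
  the slope factor is a Tobler-style anisotropic correction
  `exp(-3.5 |g + 0.05|)` normalised to 1 on flat ground (an isotropic
  flag exists because the reference tooling's setting is unknown). The
  shipped speed table (path 5, savanna 4, residential 4, forest 3,
  other 3, rice field 2, water 0.5 km/h) is a documented stand-in; no
  acceptance value depends on it. Diagonal steps cost √2 cell lengths,
  so flat-surface times overshoot the straight line by at most the octile
  bound of ~8.3%.

Method comparisons average per-route absolute differences and relative
differences (absolute values keep under- and over-estimates from
cancelling); routes with zero reference time are excluded from the
relative mean and counted.

## Population summaries

`bin_population()` reproduces the accessibility-table shape: first bin
closed on both sides, subsequent bins left-open/right-closed, distance
edges {0, 1, 2, 5, 10, 20, 30} km and time edges {0, 30, 60, 120, 180,
240, ∞} min, with population weight 1 per building by default (population
is inferred from building counts; weights are configurable).
`vulnerable_sites()` flags households strictly more than 60 min from
*both* the nearest PHC and the nearest CHS, recording the rainfall
scenario. Kriging interpolation of the original workflow is deliberately
replaced by inverse-distance weighting for visualisation only — no
quantitative output depends on the surface, and IDW avoids an unstated
variogram model.

## Numerical choices and degenerate inputs

* Coordinates are local planar metres (origin lower-left); GeoJSON files
  carry a `crs` note and GPX goes through an invertible equirectangular
  mapping anchored at a configurable reference point.
* Snapping ties between equidistant edges break to the lowest edge id;
  ties between equidistant facilities break to the lowest facility id.
* Zero-length routes (origin = destination) are valid and take 0 minutes;
  buildings disconnected from every facility are flagged with infinite
  distance, never dropped.
* Noiseless fits (σ ≈ 0) short-circuit the variance share to `NA` rather
  than 0/0; `variance_share()` errors explicitly in that case.
* The AIC term-deletion sanity check is exercised on data generated with
  decisively non-null effects; at the published effect sizes the rainfall
  term is only marginally identified from 168 track-level rainfall draws
  (its expected |t| is near the AIC threshold of √2), so a universal
  deletion inequality would be a coin flip by construction, not a defect.

## Known limitations

* Parameter recovery of land-cover contrasts carries a small attenuation
  (~0.05–0.08 km/h on the water effect) from pairs near segment
  boundaries whose measured label differs from the generating one; it
  stays well inside the published SEs and does not touch the rainfall,
  fatigue or variance-share targets.
* The friction comparator builds the full cell graph in memory; at the
  default 400 × 400 grid this is ~2.5 M directed edges, so the pipeline
  demo uses coarser grids.
* Travel times are for healthy walkers without rest breaks, one way, on a
  static network — the same scope limits the source analysis states.
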