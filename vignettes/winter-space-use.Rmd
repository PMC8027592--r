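---
title: "Modelling winter space use under snow and supplemental feeding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling winter space use under snow and supplemental feeding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(snowrsf)
```

## The problem

Alpine ungulates such as roe deer are constrained in winter by snow, which
buries forage and hampers movement, and increasingly by supplemental
feeding sites that concentrate food at points in the landscape. `snowrsf`
implements an analysis pipeline that quantifies how these two forces
jointly shape winter space use, how stable the resulting spatial pattern
is from year to year and decade to decade, and how it would shift under
warmer snow regimes. Because the original telemetry and hydrological snow
layers are not redistributable, the package pairs the analysis with a
synthetic study system whose ground truth is known exactly, so every
stage of the pipeline can be tested end to end.

## The model

Space use is modelled with a resource selection function (RSF) in the
exponential form. For a raster cell with canopy cover $CC$ (0 = open,
1 = forest), monthly mean snow depth $SD$ (cm) and 3D path distance
$Dist_{FS}$ (m) to the nearest supplemental feeding site, the relative
probability of use is

$$Rp = \mathrm{LinScale}\!\left(\exp\!\left[\hat\beta_1 CC +
\hat\beta_2 SD + \hat\beta_3 \tfrac{1}{Dist_{FS}} +
\hat\beta_4 \tfrac{SD}{Dist_{FS}}\right]\right),
\qquad
\mathrm{LinScale}(x_i) = \frac{x_i - \min(x)}{\max(x) - \min(x)}.$$

The reciprocal distance ("proximity") is used instead of distance itself
because a linear effect of distance far beyond an animal's perception
range is biologically unrealistic. The interaction term lets feeding-site
attraction strengthen under deep snow. Coefficients are estimated by
logistic regression on a used/available design: telemetry fixes
(case = 1, one randomly selected fix per animal per day to curb
autocorrelation) against an equal number of random points (case = 0)
drawn uniformly from the population's 99% kernel-density home range
(bivariate normal kernel, reference bandwidth
$h_\mathrm{axis} = \sigma_\mathrm{axis}\, n^{-1/6}$). An intercept is
estimated but excluded from prediction: the exponential RSF has none, and
the linear 0–1 scaling absorbs any constant offset (asserted by a test).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| isopleth level | 0.99 | – | home-range mass defining availability |
| used:available ratio | 1:1 | – | design balance |
| `dist_floor_m` | half a cell (50 m) | m | keeps $1/Dist_{FS}$ finite at the sites; the analysis does not resolve behaviour below cell scale |
| `n_bins` | 10 | – | quantile classes for binned maps and validation |
| `k_folds` | 5 | – | cross-validation folds, stratified by case |
| `n_compare_points` | 1000 | – | shared random points per comparison batch |
| snow-cover threshold | 5 | cm | a day counts as snow-covered above this depth (strict inequality) |
| months | Nov–Apr | – | the winter season |

## The synthetic study system

`generate_dem()` builds a valley running west–east with ridges to the
north and south (400–3500 m, 100 m cells, correlated noise), emulating a
mid-altitude alpine valley at a deer population's upper range limit.
`generate_snow_days()` produces daily snow depths as
$\max(0,\; a\,(elev - snowline_m - shift) + base_m + anom_{m,y} +
\varepsilon_d)\cdot s$ with the snowline lowest in mid-winter, a
lapse of 0.08 cm per m, a seeded interannual anomaly per winter-month,
and scalar day-to-day noise; depths are therefore monotone in elevation
and monotone decreasing in the scenario's snowline shift, which makes
the scenario contrasts exact by construction. Two regimes encode the
study contrast: the *historical* regime is interannually variable
(anomaly SD 15 cm) in every month; the *contemporary* regime is
snow-scarce and nearly constant (mean −12 cm, SD 1.5 cm) in December,
January and April while staying variable mid-winter. The two periods
also differ in feeding-site intensity: 20 sites at ≥ 400 m spacing
historically versus 95 sites at ≥ 150 m spacing contemporarily, placed
below 1500 m. Forecast regimes (*intermediate*, *severe*) shift the
snowline up by 300 and 600 m and scale depths by 0.85 and 0.70.

Telemetry is simulated from a known ground truth
($\beta_{CC} = 0.8$, $\beta_{SD} = -0.05$ per cm, $\beta_{prox} = 300$ m,
$\beta_{inter} = 5$ m/cm — the signs and orders of magnitude a winter-
constrained browser should show) as independent daily cell draws over
the whole landscape with weight $\exp(\beta^\top x)$; the exponential
weights confine use to low elevations without any hard support boundary,
which keeps the used/available density ratio exactly log-linear. The
generator deliberately omits movement autocorrelation (the pipeline
subsamples to one fix per animal-day precisely to break it), diel
activity cycles, and any real climate-model coupling; passing tests
therefore demonstrate correctness of the estimation and comparison
machinery, not realism of fine-scale movement behaviour.

## Numerical choices

* **Percentiles and quantile bins** use linear interpolation between
  order statistics (R's default type 7); bin lookup is right-closed, so
  a value equal to an interior edge falls in the lower bin. `-Inf`/`+Inf`
  sentinels route out-of-range predictions into the end bins.
* **Path distance** uses 8-connected Dijkstra with step cost
  $\sqrt{planar^2 + \Delta elev^2}$; on flat terrain this overestimates
  the Euclidean distance by at most 8.3% (octile-metric bound), which is
  accepted and tested.
* **Kappa weights** grow linearly with rank distance,
  $v_{ij} = |i-j|/(n_{bins}-1)$: "degree of rank disagreement" read as
  proportional to rank distance. Quadratic weights are available via an
  argument; note that the textbook $\kappa = -1$ for a reverse-image map
  is attained exactly under quadratic weights, while linear weights give
  about −0.52 for uniform marginals.
* **Kendall's tau** is the tie-corrected tau-b computed by mergesort
  inversion counting, with exact permutation p-values for $n \le 8$ and
  the tie-corrected normal approximation otherwise; two-sided throughout.
* **Logistic fit**: IRLS with deviance tolerance $10^{-10}$ and at most
  100 iterations; separation raises an error rather than returning
  divergent coefficients.
* **Seeds**: every stage seed is derived deterministically from one
  master seed (`derive_seed()`), so a full experiment is byte-identical
  under the same configuration; the artifact manifest records md5 hashes.
* Distances and coordinates are planar metres throughout (the
  feeding-site proximity coefficient, ~300, is only interpretable with
  $Dist_{FS}$ in metres); rasters are exchanged as plain-text ESRI ASCII
  grids and point sets as CSV.

## Design choices that were genuinely open

* **Validation extent.** Area-adjusted frequency validation is computed
  over the availability polygon (each fold's Rp surface is masked to the
  99% kernel before binning, `mask_surface()`): the model contrasts use
  against that region, and including the vast uninhabitable alpine area
  would fill half the quantile bins with cells of essentially zero
  expected use, so that their observed frequencies tie at zero and the
  rank correlation degenerates into noise.
* **Coefficient recovery vs the pooled fit.** The pipeline pools all
  winter-months into one logistic fit with a single intercept, as the
  published design does. In simulation this is detectably misspecified:
  each month layer has its own availability normalizing constant, and
  absorbing them into one intercept attenuates the snow and interaction
  slopes by a small amount (one to two standard errors at this scale).
  The package therefore ships `recovery_experiment()`, a single-layer
  benchmark on which the used/available logistic estimator is exactly
  consistent; the test suite checks slope recovery there, and treats the
  pooled fit's validation (AUC, k-fold tau) on the full experiment.
* **Null calibration of the k-fold tau.** Under case-label permutation
  the per-fold tau is large in magnitude for a structural reason: the
  held-out "used" sample is a used/available mixture and remains
  spatially concentrated, so whatever weak gradient the refitted null
  model happens to have aligns with it — with an exchangeable sign. The
  calibrated quantity is therefore the signed mean across replicates
  (centred at zero), and the suite additionally simulates telemetry from
  an all-zero truth, under which the per-fold |tau| itself is small.
* **Available points inherit the month** (and hence the snow layer) of
  their paired used group; the monthly covariate structure requires some
  assignment and this keeps the 1:1 balance month by month.
* **One kernel per period**, built from all of that period's
  relocations, defines availability for both fitting and the comparison
  points, mirroring the two separate period models (no period
  interaction terms).
* **November is excluded from the ANOVA stage** (few map pairs), though
  its kappas are still computed; per-fold validation refuses to score
  fewer than 10 held-out used points.
* **Scenario comparisons share one bin scheme**: the 10 quantile edges
  are pooled from the contemporary model's monthly predictions across
  the study and reused for every map — historical, contemporary and
  forecast — so bin ranks are comparable everywhere.

## Problem sizes

The default experiment uses an 80 × 80 grid of 100 m cells, three
winters per period, 30 snow days per winter-month, 24/23 animals with 10
telemetry days per winter-month (over 4000 used points per period after
subsampling, matching the scale of the study it emulates), 1000 shared
comparison points and 5 folds; the recovery benchmark uses 140 animals
for one winter-month (4200 used points). A full experiment runs in a few
seconds on one CPU.

## Known limitations

Telemetry is a point process, not a movement model; kappa comparisons
use a single shared point sample per batch (sampling error is common
across categories by design, so category contrasts are paired); the
8-connected path distance slightly overestimates geodesics; there is no
coordinate-system handling beyond planar metres; and the snow generator
reproduces the statistical structure the analysis needs (elevation
lapse, seasonal cycle, per-month interannual variance, scenario shifts),
not hydrological realism.

## Reproducing the analysis

```{r, eval = FALSE}
res <- run_experiment(default_run_config(1), outdir = "results/experiment")
res$models$contemporary
res$validation$contemporary$kfold
aggregate(kappa ~ category + month, res$kappa_records, mean)
res$scenario_summary
```

The numbered scripts under `analysis/` walk through the same pipeline
stage by stage and write their tables under `results/`;
`scripts/acceptance.R` recomputes the headline quantities from scratch
for a given seed.
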