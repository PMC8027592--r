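# snowrsf

Winter space use of alpine ungulates under snow and supplemental
feeding: resource selection functions, map validation, and temporal map
comparison, with a fully synthetic and seeded study system.

## The problem

At the upper altitudinal range limit of a species like roe deer, winter
distribution is squeezed between two forces: snow depth, which buries
forage and restricts movement, and supplemental feeding sites, which
concentrate food at fixed points. Both have changed over recent decades
— snow has become scarcer and more erratic at low-to-mid elevations,
while feeding-site networks have densified — and the package quantifies
how the two interact to reshape where animals spend the winter, how
stable that pattern is between years and decades, and how it shifts
under warmer snow scenarios.

## The model

Relative probability of use for a raster cell is the exponential RSF

    Rp = LinScale( exp[ b1*CC + b2*SD + b3*(1/Dist_FS) + b4*(SD/Dist_FS) ] )
    LinScale(x_i) = (x_i - min x) / (max x - min x)

with `CC` canopy cover (0/1), `SD` monthly mean snow depth (cm) and
`Dist_FS` the 3D path distance (m) to the nearest feeding site.
Coefficients come from a used/available logistic regression: one
telemetry fix per animal per day (case = 1) against an equal number of
uniform points from the population's 99% kernel home range (case = 0).
Validation uses ROC AUC, 5-fold cross-validation scored by Kendall's
tau on area-adjusted use frequencies across 10 quantile bins, and a
temporal hindcast of the contemporary model onto the historical period.
Monthly `Rp` maps are compared by rank-disagreement-weighted Cohen's
kappa at 1000 shared random points (10 pooled quantile bins), with
per-month ANOVA + Tukey tests across comparison categories and
subtraction maps (later minus earlier, bins −9…+9).

Because the original telemetry and snow layers are not shipped, a
synthetic module generates the whole study system — valley DEM
(400–3500 m), elevation-dependent daily snow with per-month interannual
variance, two feeding-site layouts (20 sparse vs 95 dense sites), and
telemetry sampled from a known ground-truth RSF — so the pipeline is
testable end to end against a known answer.

## Worked example

```r
library(snowrsf)
res <- run_experiment(default_run_config(1))
res$models$contemporary
```

```
rsf_model (4140 used / 4140 available, logLik -2342.9)
              beta          se
cc      0.77091228 0.090190735
sd     -0.06187856 0.007041526
prox  287.04677294 6.723392723
inter   4.41438177 0.516072098
```

The planted truth was `cc = 0.8, sd = -0.05, prox = 300, inter = 5`:
deer select forest, avoid deep snow, are attracted to feeding sites,
and more so when snow is deep. Validation of the same run:

```
        model                              mode   auc mean_tau max_fold_p
   historical                           spatial 0.950    0.866   3.16e-03
 contemporary                           spatial 0.942    0.859   1.23e-03
 contemporary temporal (hindcast to historical)    NA    0.989   7.77e-05
```

and the temporal comparison reproduces the expected pattern — the mean
year-to-year kappa is higher in the contemporary period in the
snow-stabilised months (Dec/Jan/Apr), and the inter-decadal kappa is
the lowest category in every month:

```r
aggregate(kappa ~ category + month, res$kappa_records, mean)
res$scenario_summary
```

```
       regime snowline_shift_m top_bin_cells_upslope total_cover_days
 contemporary              150                 281.2          2392298
 intermediate              300                 358.0          2215513
       severe              600                 489.7          1866827
```

Warmer scenarios monotonically push high-`Rp` area upslope (cells above
1500 m in the top three bins) and erase snow-cover days grid-wide.

The numbered scripts in `analysis/` run the same pipeline stage by
stage (landscape and snow trends, telemetry and design, RSF fits,
validation, map comparison) and write their tables under `results/`.

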