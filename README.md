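# sinkstability

Pixel-level analysis of the trend and stability of terrestrial carbon
sinks, for ecologists studying how overlapping ecological-engineering
programmes shape net ecosystem productivity (NEP). The package takes
gridded annual NEP records (a pixel is a carbon sink when NEP > 0) plus an
integer mask counting how many engineering projects cover each pixel
(overlap strata 0–5), and answers four questions:

1. **How is each pixel's sink changing?** Ensemble empirical mode
   decomposition (EEMD) splits each annual series into intrinsic mode
   functions and a nonlinear secular trend (the residual). The residual's
   year-to-year rates classify the pixel as *increasing*, *decreasing*, a
   *positive reversal* (decreasing → increasing at a turning point), a
   *negative reversal*, or *nonsignificant* under a Monte-Carlo surrogate
   test.
2. **How stable is the sink?** The detrended coefficient of variation

   ```
   NEP_cv = sqrt( Σ (NEP_detrend,year − NEP_mean)² / N ) / NEP_mean,
   NEP_detrend,year = NEP_year − (a·year + b) + NEP_mean
   ```

   (population SD of the linearly detrended series over the mean), classed
   into five ordinal levels — stable … unstable — by exact Fisher–Jenks
   natural breaks.
3. **What drives stability?** Natively implemented stochastic
   gradient-boosted regression trees (75 % bag fraction, slow learning,
   shallow trees, early stopping) attribute the binary stable/unstable
   response to five climate drivers (TEM, PRE, SOIL, VPD, RAD) and five
   human drivers (CO2, N2O, LUC, POP, GDP) via Friedman relative
   influence, with repeated stratified 10-fold cross-validation scored by
   AUC (≥ 0.9 excellent, 0.8–0.9 good, 0.7–0.8 accurate, 0.6–0.7 poor).
4. **What happens under future scenarios?** The fitted classifiers project
   per-pixel trend (enhanced / degraded / other) and stability (stable /
   unstable / other) classes under shifted covariate sets, aggregated per
   overlap stratum.

A seeded synthetic-data generator with full ground truth (trend shapes,
turning points, true CV, driver weights, stratum composition) makes every
stage testable end to end without the proprietary source rasters.

## Worked example

```r
library(sinkstability)

res <- run_sink_analysis(
  config    = synthetic_config(grid_shape = c(12, 20), trend_rate = 2,
                               noise_sd = 6),
  scenarios = list(low  = list(deltas = c(SOIL =  1),           year = 2060),
                   high = list(deltas = c(SOIL = -1, CO2 = 1),  year = 2060)),
  hyper     = brt_config(n_trees = 500),
  seed      = 99)
res
#> <sink_analysis> 240 pixels x 38 years
#> trend labels:
#>        decreasing        increasing negative_reversal    nonsignificant
#>                49                48                48                46
#> positive_reversal
#>                49
#> stability classes:
#>  1  2  3  4  5
#> 55 68 21 37 59
#> climate/human influence (national):
#>   stratum   group influence
#>  national climate  21.86158
#>  national   human  78.13842
```

The five trend-kind bands of the synthetic world (48 pixels each) are
recovered almost perfectly — the `flat` band is the `nonsignificant`
count — and the five stability classes follow the grid-wide natural
breaks of the detrended CV. The influence split leans on the single
strongest correlated driver (here CO2), the usual greedy-tree behaviour
under collinearity discussed in the methods vignette. Individual stages are ordinary tibble-in /
tibble-out functions (`decompose_grid()`, `classify_trend_grid()`,
`classify_stability()`, `stratified_attribution()`,
`project_scenario()`, …) that chain with the pipe; `plot_trend_map()`,
`plot_stability_map()`, `plot_influence()` and `autoplot()` draw the
standard figures, and `write_analysis_outputs()` writes the CSV/JSON
artefacts.

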