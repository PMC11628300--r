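---
title: "Methods: nonlinear sink trends, detrended-CV stability, and boosted-tree attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonlinear sink trends, detrended-CV stability, and boosted-tree attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinkstability)
```

This vignette documents the models behind the package, the parameters a
user might tune, the numerical choices made where the methods are
genuinely open, and what the synthetic validation does and does not show
about real data.

## The analysis in one paragraph

Each pixel of a gridded annual NEP record is decomposed with ensemble
empirical mode decomposition; the low-frequency residual is read as the
pixel's nonlinear secular trend and classified into monotone increase or
decrease, positive or negative reversal with a turning-point year, or
nonsignificant under a surrogate Monte-Carlo test. Sink stability is the
coefficient of variation of the linearly detrended series, classed into
five ordinal levels by exact Fisher–Jenks natural breaks computed once for
the whole grid. Stability is attributed to five climate and five human
drivers with stochastic gradient-boosted regression trees and Friedman
relative influence, stratified by the number of overlapping ecological
projects, and the fitted classifiers project trend/stability classes under
shifted covariate scenarios.

## EMD and its ensemble variant

Sifting follows the classical scheme: natural cubic splines through the
local maxima and minima form upper and lower envelopes, the envelope mean
is subtracted, and the candidate is accepted as an intrinsic mode function
(IMF) once the Cauchy-type criterion `sum(m^2)/sum(h^2) < 0.2` holds or 10
sifts have been spent. Decomposition stops when the remainder has fewer
than two interior extrema (or is numerically constant); that remainder is
the residual. Completeness — IMFs plus residual reproduce the input — is
exact by construction and asserted to 1e-9 in the tests.

Boundary handling matters more than anything else on 38-point records. The
envelopes use mirror extension: the first/last two extrema are reflected
across the series boundaries before spline fitting, and an endpoint is
promoted to an extremum only when it lies beyond the nearest interior
extremum. Clamping both envelopes to the endpoints (a common shortcut) was
rejected: it forces the residual to interpolate the noisy first and last
observations, which on short records manufactures spurious end-of-record
reversals.

EEMD decomposes `ensemble_size` white-noise-perturbed copies and averages
IMFs (aligned by index, zero-padded) and residuals. Defaults are the
conventional 100 members with noise at 0.2 of the series SD; neither value
is critical, and `paired = TRUE` uses ±noise pairs for even ensembles so
the reconstruction defect vanishes identically rather than at the 1/√m
Monte-Carlo rate. The per-series IMF cap defaults to the dyadic limit
⌊log2 n⌋ + 1. Noise is drawn from R's RNG, so a seed makes any
decomposition bit-reproducible; grid runs give every pixel a child seed
indexed by pixel id, making results independent of pixel order.

## Trend classification

The residual's first differences give the trend's year-to-year rate. A
monotone rate sequence labels the pixel increasing or decreasing by the
sign of the residual net change; a single interior sign change labels it a
reversal, typed by the sign sequence (− then + is a positive reversal),
with the turning point at the vertex year. Three guards handle short-record
pathologies, all tunable:

* sign changes within `guard = 3` years of either end are ignored
  (end-effect protection);
* a reversal is only declared when each of its two segments carries at
  least `min_segment = 0.2` of the residual's total variation — otherwise
  the shape is a monotone trend with a small end wiggle and is labelled by
  its net change;
* residuals with several admissible sign changes (possible under heavy
  noise; the four-shape taxonomy does not cover them) are labelled by the
  segments around the last turning point and flagged `complex`, with a
  warning.

### Significance

No canonical test exists for the significance of an (E)EMD residual trend,
so the package uses a surrogate Monte-Carlo design. The statistic is the
residual's total variation (the sum of absolute year-to-year changes)
studentised by the SD of the oscillatory part `values − residual`. For a
monotone residual the total variation reduces exactly to the absolute net
change — the natural trend magnitude — while remaining sensitive to
reversal shapes, whose segments cancel in the plain net change; a
symmetric reversal would otherwise be undetectable in principle. The null
distribution is the same statistic computed on decompositions of `n_null`
surrogates: iid Gaussian noise by default, or phase-randomised copies that
preserve the sample spectrum. The p-value is the Monte-Carlo rank
`(1 + #(null ≥ observed)) / (n_null + 1)`; with matched decomposition
settings on both sides the statistic is pivotal under the white-noise
null, so the test is exactly calibrated, which the acceptance suite
verifies (type-I rate within the binomial band around α = 0.05 at 200
series × 1000 surrogates).

Because the statistic is scale-free, its null depends only on the record
length and decomposition settings. Grid runs therefore compute one null
sample per grid and share it across pixels — statistically identical to
per-pixel surrogates and orders of magnitude cheaper. By default the
shared null uses single-member (plain EMD) surrogates even when pixels are
decomposed with a full ensemble; the ensemble-averaged residual of pure
noise is slightly smoother than a single-member one, so this choice is
mildly conservative. `match_null = TRUE` restores the exactly matched
null at proportional cost.

## Stability

The printed definition of the detrended series is linear: subtract the OLS
line and add back the mean. The coefficient of variation uses the
population (divide-by-N) standard deviation of those detrended values over
the mean. Both choices are kept exactly as defined; an EEMD-residual
detrending variant (`detrend = "eemd"`) is exposed because detrending
prose and detrending equations differ in parts of the literature, but the
linear form is the default. Pixels whose mean NEP is not positive are not
sinks, are flagged, and are excluded from the stability map.

Classing uses Fisher–Jenks natural breaks: the exact dynamic programme
over contiguous partitions of the sorted values, O(k·n²) with prefix sums,
verified against exhaustive search on all small instances. Breaks are
computed once over the whole grid's cv distribution and applied everywhere
(one national classification); values tied with a break go to the lower
class, deterministically. Five-way classing of a degenerate (near-constant)
cv distribution is an error, not a silent fallback.

## Driver attribution

The boosted-tree core is written in the package (C++): stagewise
regression trees on the negative gradient, squared-error loss for
continuous responses and Bernoulli deviance with Newton leaf updates for
binary ones. Defaults: learning rate 0.01, depth 3, at most 2000 trees,
bag fraction 0.75 (each tree sees a random 75 % subsample; the held-out
25 % monitors deviance), early stopping after 50 iterations without
out-of-bag improvement, minimum terminal node of 10. Influence accounting
is Friedman's: each split's deviance reduction accrues to the split
variable; per-driver totals over the kept ensemble are normalised to sum
to 100 %. Writing the booster natively keeps that accounting auditable;
an installed gradient-boosting library is used in the test suite as an
independent cross-check of predictions and importance ranking, never as
the implementation.

The stability response is binarised as classes 1–2 = stable, 4–5 =
unstable, middle class excluded (configurable); the five-level vocabulary
makes this the symmetric choice. Model skill is repeated stratified
k-fold cross-validation (10 folds × 10 repetitions by default), scored by
rank-based AUC — identical to the Mann–Whitney statistic — for binary
responses and R² otherwise. AUC grades use left-closed bands: ≥ 0.9
excellent, [0.8, 0.9) good, [0.7, 0.8) accurate, [0.6, 0.7) poor; the
published bands leave the boundary points unassigned, so boundaries go to
the higher band, and below 0.6 is "fail". Fits sort rows canonically
before boosting, so results are a function of the data, not of row order.
Strata with fewer usable rows than `min_rows` (default 200) are skipped
with a warning rather than fitted badly.

## Scenario projection

Trend labels map to the binary training vocabulary as increasing +
positive reversal = enhanced, decreasing + negative reversal = degraded;
nonsignificant pixels are excluded from training and reappear as "other"
at projection time, as does the excluded middle stability class. Projection
thresholds at probability 1/2 with exact ties going to "other". Projection
is a pure function of the fitted models and the scenario grids; scenario
covariates are accepted as the same tables as historical drivers (mean
shifts via `generate_scenario_drivers()` stand in for climate-model
output, which is out of scope).

## The synthetic world

`generate_nep_grid()` builds each pixel as trend + optional sinusoid + iid
Gaussian noise. Defaults emulate a 38-year national NEP record: mean level
300 gC m⁻² yr⁻¹, trend magnitude 1 gC m⁻² yr⁻¹ per year, noise SD
8 gC m⁻² yr⁻¹ (interannual swings of roughly ±16), mid-record turning
point (2000) for reversal pixels. Reversals are piecewise-linear by
default so the turning point and the noiseless detrended CV are exact
bookkeeping (a smooth quadratic vertex is available). Gaussian noise is an
assumption — the interannual distribution of real NEP is not specified
anywhere — and is flagged as such. Driver tables are constructed so each
driver's correlation with the stability response is proportional to its
configured weight (drivers with zero weight are independent of the
response), optionally with different weight vectors per overlap stratum;
the overlap mask apportions strata by largest remainder, exact to one
pixel.

What the generator does **not** emulate: spatial autocorrelation (pixels
are independent), autocorrelated or heteroskedastic interannual noise,
mechanistic vegetation dynamics, and real scenario structure. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers known
structure under realistic magnitudes and record lengths — not that any
particular real-world attribution is correct.

## Validation choices and problem sizes

* Noiseless recovery runs use the degenerate single-member decomposition
  (plain EMD): on noiseless data the ensemble noise has no mode-mixing to
  repair and only perturbs an otherwise exact residual. Noisy runs use the
  full EEMD(100, 0.2).
* The noisy recovery experiments set the noise SD to 25 % of each trend
  shape's signal range, a regime where classification is hard but
  feasible; recovery is measured over 20 seeds × 4 shapes × 25 pixels.
* The end-to-end world uses a 50 × 50 grid with trend magnitude
  3 gC m⁻² yr⁻¹ per year against noise SD 8 — the same ~20 % noise-to-range
  regime for the hardest (reversal) shapes — with human-dominant driver
  weights in overlap strata 0–2 and climate-dominant weights in 3–5.
  Share recovery is judged against the truth table's counting at three
  binomial standard errors plus a small allowance for residual
  misclassification; the importance check asks only that the constructed
  climate-vs-human ordering is recovered in every analysed stratum.
* Cross-validation in the acceptance script runs the full 10 × 10 layout
  on the national stability table.

## Known limitations

* EMD end effects are mitigated, not eliminated; trend estimates in the
  first and last ~3 years remain the least reliable, which is why the
  classification guard band exists.
* The residual of a genuinely trendless but strongly autocorrelated series
  can pass the white-noise surrogate test; the phase-randomised surrogate
  option is the appropriate null in that situation.
* Relative influence inherits the usual tree-ensemble behaviour under
  collinearity: correlated drivers share influence, so grouped (climate
  vs human) sums are more robust than single-driver rankings.
* Jenks classing is O(n²) in the number of classified pixels; beyond ~10⁵
  pixels, classing a random subsample and applying the breaks grid-wide is
  the practical route.
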