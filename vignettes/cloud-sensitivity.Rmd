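---
title: "Quantifying vegetation sensitivity to cloud cover: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vegetation sensitivity to cloud cover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloudsens)
```

## The problem and the model

Cloud fraction (CF) is a single observable that bundles the two
opposing ways clouds act on photosynthesis: more cloud means more
precipitation (helping water-limited vegetation, with a soil-moisture
delay) and less shortwave radiation (hurting energy-limited vegetation
immediately). `cloudsens` estimates the net effect as a regression
slope between standardized anomalies and asks how that slope is
organized by hydroclimate, summarized by the humidity index
HI = mean annual precipitation / potential evapotranspiration (arid
HI < 1, humid HI > 1; the exact boundary belongs to neither class).

Every estimator in the package is ordinary least squares with an
intercept and two-sided Student's-t P-values. We deliberately match
that simplicity: no autocorrelation or spatial-dependence corrections
are applied, so P-values are descriptive rather than strictly
calibrated (a known limitation, see the end of this vignette).

### Standardization

Raw series are converted to standardized anomalies in two steps
applied *per calendar period* (calendar day, 8-day period, or month)
across years: remove the interannual linear trend fitted to that
period's values, then divide the residual by its cross-year standard
deviation. After both steps each calendar period has mean 0 and
standard deviation 1 across years — the contract the test suite
asserts at 1e-10. Degenerate periods (fewer than `min_valid_years = 3`
valid years, or zero variance) become missing rather than infinite; a
two-point standard deviation carries no information, which is why the
default minimum is 3. Gridded multi-decadal inputs are always
detrended; flux-tower records are only detrended when they span at
least 10 years (short records cannot support a stable per-calendar-day
trend), mirroring common site-data practice.

Calendar conventions: daily data drop Feb 29 so every year has 365
days; the 8-daily calendar has 46 fixed periods restarting each Jan 1
(the final period is 5 days). Composites and box means require at
least 50% of their member values to be valid — a common
remote-sensing compositing rule; the choice is ours, stated here
because upstream conventions differ.

### Sensitivity estimators

* **Univariate** `S = dGPP*/dCF*`: on standardized inputs the slope
  equals the Pearson correlation; this identity is tested to 1e-10.
* **Partial** (`PA*` and `PAR*`, or the nine ISCCP cloud-type
  fractions): collinearity is diagnosed with variance inflation
  factors, `VIF_j = 1 / (1 - R2_j)` from auxiliary regressions. With
  exactly two regressors both auxiliary R-squared are the same squared
  correlation, so the implementation computes the pair's VIF once from
  it — equality is then exact, not approximate. The usual `max VIF < 5`
  rule is reported as a flag and never silently masks results.
* **Time-lagged** `S(tau)`: the regression of `GPP*(t)` on
  `CF*(t + tau)` over the valid index overlap; `tau = 0` reduces
  bit-identically to the univariate estimator.
* **Lag-response profile**: a joint regression on `PA*(t), PA*(t-1),
  ..., PA*(t-l)` with `l = 8` by default (64 days at 8-daily
  resolution). The effective response period is the lag of the largest
  coefficient that is significant at `alpha = 0.001`. Exact ties go to
  the smaller `|tau|` — preferring the more instantaneous mechanism —
  a choice that matters only on degenerate inputs.
* **Annual attribution**: year-to-year differences `dGPP ~ dCF + dT2m
  + dq`, pooled over a 3x3 moving window (longitude wraps, latitude
  truncates), each neighbour cell contributing rows with equal
  weight. Differencing removes any shared linear trend exactly (tested
  to 1e-10). Incremental variance explained of a regressor is the
  R-squared gain over the baseline model holding all other regressors.
  Whether neighbouring cells should be pooled as independent rows or
  averaged first is genuinely open; we pool rows, which multiplies the
  sample size by the window area and is the interpretation consistent
  with "increasing the sample size" motivations for windowed
  regression.
* **Projection**: `dGPP_CF = beta_CF x dCF` with CF changes anchored
  to the mean of the first five years (so the baseline-window mean of
  the result is exactly zero), and `gammaGPP_CF = beta_CF x gammaCF`
  for trends. `beta_CF` is held fixed over the projection horizon —
  the standard constancy assumption, inherited knowingly.

Minimum sample sizes default to 30 paired samples for daily/8-daily
fits and 12 for monthly; missing rows are removed listwise. These
guards are our choices where conventions are silent; they exist to
prevent degenerate fits, not to tune results.

### Hydroclimate utilities

HI uses the ratio of long-term means (not the mean of yearly ratios —
the two differ whenever annual totals covary, and the ratio of means
is the defined quantity). PET uses the FAO-56 reference-crop
Penman-Monteith formulation; the equation family has variants, and
where only "Penman-Monteith" is specified we use FAO-56 as the
best-documented reference standard, with available energy taken as
LE + H when net radiation is not measured. The active season is months
with climatological T2m > 0 degC, restricted in arid cells to months
whose running cumulative precipitation fraction lies in (0.10, 0.90]
evaluated at month end (half-open on the left so a month that merely
reaches 10% is excluded; the endpoint handling is our determinization
of the 10-90% rule). Southern-hemisphere arid cells accumulate July
through June so wet seasons straddling New Year are not split.

## The synthetic world

Real global products cannot be redistributed or downloaded at test
time, so correctness is established by parameter recovery on a seeded
synthetic world whose ground truth is known exactly. Per pixel, on the
standardized-anomaly scale:

```
PA*  =  a_c CF* + e1,   PAR* = -b_c CF* + e2
GPP* = w_PA(HI) PA*(t - lag(HI)) + w_PAR(HI) PAR*(t) + e3
```

with `a_c = b_c = 0.7`, residual sds 0.5, and logistic weights in
log(HI) that cross at HI = 1 — so the ground-truth CF sensitivity
`S_true = w_PA a_c - w_PAR b_c` is positive in arid and negative in
humid cells. HI is log-spaced from 0.2 to 5 across longitude with
multiplicative jitter (sd 0.15 in log space), giving the spread that
regressions of sensitivity on log(HI) need. Precipitation lags default
to 0 periods for HI >= 0.8, 1 for 0.4 <= HI < 0.8 and 2 for HI < 0.4
(8 and 16 days) — delays within one month, larger in more arid cells,
and kept modest so that monthly compositing retains a positive arid
signal; lags are applied as integer shifts with the leading periods of
GPP set missing to avoid wrap-around artifacts. Raw fields are
mean + seasonal cycle + linear trend + scale x anomaly with physical
floors (CF clipped to [0, 1], PA/GPP/PET floored at 0; floor events
are below 1% under the defaults so they do not distort regression
tests). The default trend structure has CF declining at 0.002 per
year, the condition under which the projection stage should move
productivity from arid to humid cells. Mean climatologies scale with
HI (wetter cells rain more and support more GPP) and latitude
(temperature), and PET is generated consistently with the assigned HI
so the hydroclimate stage recovers it. Truth arrays store exactly the
values used in generation, never re-estimates.

What the generator does *not* emulate: satellite retrieval artifacts
(cloud-contaminated optical indices, swath gaps) beyond an optional
random missing mask; spatially correlated weather; nonlinear or
saturating responses; vegetation types. Passing recovery tests
therefore demonstrates that the estimators measure what they claim on
data obeying their assumptions — not that real-world retrieval biases
are handled.

Analyses that compare sensitivity across the hydroclimate gradient are
run on monthly composites: with point lags, the 8-daily instantaneous
slope in a lagged arid pixel sees only the radiation channel, while
monthly aggregation folds sub-monthly precipitation delays back into
the predictor — the same reason monthly-scale sensitivities exceed
8-daily ones in arid regions in real data.

Site records are derived from pixels by piecewise-constant expansion
to daily resolution plus daily noise on GPP and precipitation; SWin is
exactly twice PAR (the standard conversion), and record lengths are
heterogeneous by construction (including sub-3-year and over-10-year
records) so the site filters and the long-record detrend rule are
exercised. Cloud-type joint histograms distribute each pixel's total
CF over the 8x7 optical-thickness/top-pressure bins with a smooth mode
that shifts toward thick, low-topped (rain-bearing) classes when the
precipitation anomaly is high; cells sum exactly to total CF, which is
what makes the conservation tests exact.

## Numerical choices

* OLS is solved by QR; rank deficiency yields a missing result with a
  reason code, but VIFs are still reported (infinite for aliased
  columns) so collinearity gating remains possible.
* An exact fit (zero residual) reports P = 0 for nonzero coefficients
  rather than an undefined 0/0 statistic.
* Trend fits center the year index to decorrelate slope and intercept;
  this changes nothing about the slope.
* Box-mean regridding weights member cells by cosine latitude, which
  is what makes it conserve the area-weighted global mean (tested to
  1e-10); bilinear regridding clamps target points to the source hull.
* The regional 99% confidence interval is the normal half-width of the
  cosine-weighted spatial mean (weighted spatial sd times
  `sqrt(sum(w^2))/sum(w)`), i.e. spatial spread at fixed time.
  Shaded regional bands in the literature are also sometimes
  inter-model spread; both readings are defensible, the spatial-SE
  estimator is implemented and the choice is isolated in
  `area_weighted_mean()` so it can be swapped.
* Gridded text files serialize doubles with 17 significant digits, the
  minimum that makes write-read round trips bit-exact.

## Problem sizes

The shipped default world is 12 x 24 pixels by 20 years of 46 periods
(about 265k values per variable), which the full pipeline processes in
a few seconds; replicated recovery experiments use 500 replicates of
n = 920 for the bivariate regression and 200 replicates for the
lag-profile recovery. These sizes give Monte-Carlo rates stable to a
couple of percentage points across seeds while keeping a full test run
interactive.

## Known limitations

* P-values ignore serial and spatial autocorrelation, as does the
  pooled-window attribution (pooled rows from neighbouring cells are
  treated as independent). Year-to-year differencing of serially
  uncorrelated levels also induces MA(1) noise in the differences, so
  nominal standard errors there are approximate; the recovery tests
  use random-walk levels, for which the differenced model is exactly
  specified.
* The VOD night/day ratio is implemented as the literal ratio
  night/day, guarded against non-positive daytime values; the name
  admits other readings (e.g. differences) and we flag rather than
  assert the convention.
* The ISCCP reclassification requires original bin edges to nest
  within the nine-class boundaries; bins straddling a boundary are
  rejected rather than split, because splitting would require an
  intra-bin distribution assumption.
* 8-daily-to-monthly compositing assigns each 8-day period to the
  month containing its middle day; periods straddling month boundaries
  are not split.
* Projection holds `beta_CF` constant; under strong forcing or CO2 /
  acclimation effects the sensitivity itself drifts, which is outside
  the model.
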