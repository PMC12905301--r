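# cloudsens

Clouds regulate the two resources photosynthesis depends on most:
they generate precipitation (water supply) and block shortwave
radiation (energy supply). Whether more cloud cover helps or hurts
vegetation productivity therefore depends on the local hydroclimate —
in water-limited (arid) regions clouds promote gross primary
productivity (GPP) through rainfall, with a delayed response, while in
energy-limited (humid) regions they suppress it almost instantaneously
by shading. `cloudsens` is an R package for quantifying this
sensitivity end to end, aimed at ecosystem-climate analysts working
with gridded flux/cloud products or eddy-covariance site records.

## The method

All series are first reduced to standardized anomalies per calendar
period (day, 8-day period, or month): the interannual linear trend is
removed for each calendar period separately,

```
X_t = a t + b + e_t          =>   X'_t = X_t - (a t + b)
X*  = (X' - mu) / sigma
```

with `mu`, `sigma` the cross-year mean and standard deviation for the
same calendar period. The core sensitivity is then the ordinary
least-squares slope

```
S = d GPP* / d CF*
```

with a two-sided Student's-t P-value, and its partial-regression
relatives:

* `GPP* ~ PA* + PAR*` — partial sensitivities to precipitation and
  radiation anomalies; `beta_PA - beta_PAR` proxies the water-vs-energy
  balance (the two-regressor VIFs are identical by construction).
* `GPP* ~ sum_i CF_i*` — partial sensitivities to the nine ISCCP cloud
  types, with relative contributions `RC_i = beta_i / sum(beta)`.
* `GPP*(t) ~ CF*(t + tau)` — time-lagged sensitivity; a distributed-lag
  profile over `tau = 0..-8` (64 days at 8-daily resolution) locates
  the effective response period as the largest significant lag
  coefficient.
* `dGPP ~ dCF + dT2m + dq` — annual-scale attribution on year-to-year
  differences, pooled over a 3x3 moving window, with per-regressor VIF
  gating and incremental variance explained.
* `dGPP_CF = beta_CF x dCF` and `gammaGPP_CF = beta_CF x gammaCF` —
  projection of cloud-driven GPP change from CF changes and trends,
  summarized as cosine-latitude area-weighted regional series (global /
  arid HI < 1 / humid HI > 1) with 99% confidence intervals.

Hydroclimate is quantified by the humidity index HI = (long-term mean
annual precipitation) / (potential evapotranspiration), with FAO-56
Penman-Monteith PET and a meteorological active-season mask (months
with T2m > 0 degC; in arid cells additionally the 10-90% cumulative
precipitation window, accumulated July-June in the southern
hemisphere).

Because the method is validated by parameter recovery, the package
ships a seeded synthetic-world generator whose ground-truth
sensitivities are known by construction and encode the
hydroclimate-dependent coupling above.

## Worked example

```r
library(cloudsens)

res <- run_pipeline(pipeline_config(world = world_config(seed = 7)))

# hydroclimate shaping: pixel-wise monthly sensitivity vs log(HI)
res$sensitivity$hi_shaping$coefficients[2]   # -0.335 (slope per log-HI unit)
res$sensitivity$hi_shaping$r                 # -0.935

# agreement between the monthly standardized sensitivity map and the
# annual-scale attribution slope
sign_consistency(res$sensitivity$map_monthly$S,
                 res$attribution$map$beta_cf)$fraction   # 0.92

# cloud-driven GPP trend under the world's declining CF: arid pixels
# lose productivity, humid pixels gain
g  <- res$projection$gpp_trend_cf
hi <- res$hydro$hi
mean(g[hi < 1] < 0, na.rm = TRUE)   # 0.89
mean(g[hi > 1] > 0, na.rm = TRUE)   # 0.95
```

The negative slope and strong negative correlation say that the
GPP-to-cloud sensitivity falls monotonically from weakly positive in
arid cells to strongly negative in humid cells; the projection
fractions show the resulting spatial shift of productivity from arid
toward humid regions when cloud cover declines.

A thin command-line wrapper over the same functions is installed at
`inst/cli/cloudsens.R` (subcommands `simulate`, `standardize`, `hydro`,
`sens`, `attr`, `project`, `run`; exit codes 0/2/3/4 for
success/config/data/numerical errors), with a fully commented default
configuration in `inst/config/default.yaml`.

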