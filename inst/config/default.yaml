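# cloudsens default pipeline configuration.
# Every analysis threshold is a named key; generator weight/lag
# mappings keep their in-package defaults.

world:
  n_lat: 12            # grid rows (60S-60N)
  n_lon: 24            # grid columns (180W-180E)
  n_years: 20          # record length, years
  periods_per_year: 46 # 8-daily calendar
  seed: 1
  hi_range: [0.2, 5.0] # humidity-index span across the longitude gradient
  hi_jitter_sd: 0.15   # multiplicative (log-normal) HI jitter
  missing_frac: 0.0    # optional random missing-data mask

veg_gpp_floor: 0.1       # g C m-2 d-1, vegetation mask (strictly over)
vif_threshold: 5         # collinearity gate on max VIF (reported, not enforced)
alpha: 0.001             # significance level, sensitivity maps / lag profiles
min_n_subannual: 30      # min paired samples, daily / 8-daily fits
min_n_monthly: 12        # min paired samples, monthly fits
min_n_annual: 30         # min pooled rows, annual attribution
baseline_years: 5        # projection baseline window
window: 3                # attribution moving window (odd; 3, 5 or 7)
l_max: 8                 # max lag, periods (64 days at 8-daily)
min_years_detrend_sites: 10  # site records shorter than this are not detrended
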