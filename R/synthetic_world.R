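# Seeded synthetic world with known, hydroclimate-dependent ground
# truth.
#
# Per pixel, standardized-scale anomalies are generated as
#   PA*  =  a_c * CF* + e1          (cloud-precipitation coupling, +)
#   PAR* = -b_c * CF* + e2          (cloud-radiation coupling, -)
#   GPP* = w_PA(HI) * PA*(t - lag(HI)) + w_PAR(HI) * PAR*(t) + e3
# so the ground-truth CF sensitivity S = w_PA a_c - w_PAR b_c flips
# sign at the arid/humid boundary: water-limited cells (HI < 1) take
# most of their signal from (lagged) precipitation, energy-limited
# cells (HI > 1) from instantaneous radiation. Raw fields are
# mean + seasonal cycle + linear trend + scale * anomaly, with
# physical floors (CF in [0,1], PA/GPP/PET >= 0).

.world_vars <- c("cf", "pa", "par", "t2m", "q", "gpp", "pet")

default_w_pa_fn <- function(hi) 0.7 * stats::plogis(-log(hi) / 0.5)
default_w_par_fn <- function(hi) 0.7 * stats::plogis(log(hi) / 0.5)
default_lag_fn <- function(hi) {
  ifelse(hi >= 0.8, 0L, ifelse(hi >= 0.4, 1L, 2L))
}

#' Configuration of the synthetic world
#'
#' Defaults define the study conditions: a 12 x 24 grid spanning 60S to
#' 60N, 20 years of 46 8-day periods, humidity index (HI) log-spaced
#' from 0.2 to 5 across longitude with multiplicative jitter, coupling
#' weights that cross at HI = 1 so the ground-truth CF sensitivity
#' changes sign at the arid/humid boundary, and precipitation lags of
#' 0-2 periods (0-16 days), longer in more arid cells.
#'
#' @param n_lat,n_lon grid dimensions (positive).
#' @param n_years record length in years.
#' @param periods_per_year 46 (8-daily), 12 (monthly) or 365 (daily).
#' @param seed integer RNG seed; identical config + seed gives a
#'   bit-identical world.
#' @param hi_range min/max humidity index across the longitude
#'   gradient.
#' @param hi_jitter_sd sd of the multiplicative (log-normal) HI jitter.
#' @param w_pa_fn,w_par_fn monotone mappings HI -> coupling weight
#'   (decreasing / increasing respectively, crossing near HI = 1).
#' @param lag_fn mapping HI -> integer lag in periods (0 for humid
#'   cells, at most 8 anywhere).
#' @param coupling named pair `a_c`, `b_c` (> 0): anomaly-scale CF to
#'   PA / PAR couplings.
#' @param noise_sd named sds of the anomaly residuals `e1` (pa), `e2`
#'   (par), `e3` (gpp).
#' @param trend_per_year named per-variable linear trend slopes (units
#'   of the variable per year).
#' @param missing_frac fraction of raw values randomly masked missing.
#' @return a validated `world_config` list.
#' @export
world_config <- function(n_lat = 12L, n_lon = 24L, n_years = 20L,
                         periods_per_year = 46L, seed = 1L,
                         hi_range = c(0.2, 5), hi_jitter_sd = 0.15,
                         w_pa_fn = default_w_pa_fn,
                         w_par_fn = default_w_par_fn,
                         lag_fn = default_lag_fn,
                         coupling = c(a_c = 0.7, b_c = 0.7),
                         noise_sd = c(pa = 0.5, par = 0.5, gpp = 0.5),
                         trend_per_year = c(
                           cf = -0.002, pa = 0, par = 0, t2m = 0.03,
                           q = 2e-6, gpp = 0, pet = 0
                         ),
                         missing_frac = 0) {
  if (n_lat < 1 || n_lon < 1 || n_years < 2) {
    stop("grid dimensions must be positive and n_years >= 2")
  }
  if (!periods_per_year %in% c(12L, 46L, 365L)) {
    stop("periods_per_year must be one of 12, 46, 365")
  }
  if (any(coupling <= 0)) stop("coupling constants must be positive")
  # numeric checks of the weight/lag structure on a probe grid
  probe <- exp(seq(log(hi_range[1]), log(hi_range[2]), length.out = 64))
  wpa <- w_pa_fn(probe)
  wpar <- w_par_fn(probe)
  if (any(diff(wpa) > 1e-12)) stop("w_pa_fn must be decreasing in HI")
  if (any(diff(wpar) < -1e-12)) stop("w_par_fn must be increasing in HI")
  lg <- lag_fn(probe)
  if (any(lg < 0) || any(lg > 8)) stop("lag_fn must map into 0..8 periods")
  if (any(lg[probe > 1] != 0)) stop("lag_fn must be 0 for HI > 1")
  structure(
    list(
      n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
      n_years = as.integer(n_years),
      periods_per_year = as.integer(periods_per_year),
      seed = as.integer(seed),
      hi_range = hi_range, hi_jitter_sd = hi_jitter_sd,
      w_pa_fn = w_pa_fn, w_par_fn = w_par_fn, lag_fn = lag_fn,
      coupling = coupling, noise_sd = noise_sd,
      trend_per_year = trend_per_year,
      missing_frac = missing_frac
    ),
    class = "world_config"
  )
}

.res_of_ppy <- function(ppy) {
  c("12" = "monthly", "46" = "8-daily", "365" = "daily")[[as.character(ppy)]]
}

# seasonal shape: peak at mid-year in the north, flipped in the south
.seasonal_shape <- function(period, ppy, lat) {
  s <- sin(2 * pi * period / ppy - pi / 2)
  outer(s, ifelse(lat >= 0, 1, -1))
}

#' Generate the synthetic world
#'
#' @param config a [world_config()].
#' @return a `synthetic_world`: list with `config`, `lat`, `lon`,
#'   `hi_true` (matrix), `fields` (named list of raw
#'   [gridded_field()]s: `cf`, `pa`, `par`, `t2m`, `q`, `gpp`, `pet`),
#'   `anomalies` (the generated standardized-scale anomaly arrays),
#'   `scales` (per-variable anomaly-to-raw scalings), and `truth`
#'   (matrices `s_true`, `beta_pa_true`, `beta_par_true`, `lag_true`,
#'   `beta_cf_annual_true` — exactly the values used in generation).
#' @export
make_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  nlat <- config$n_lat
  nlon <- config$n_lon
  ppy <- config$periods_per_year
  npix <- nlat * nlon
  n_t <- config$n_years * ppy

  dlat <- 120 / nlat
  lat <- seq(-60 + dlat / 2, 60 - dlat / 2, length.out = nlat)
  dlon <- 360 / nlon
  lon <- seq(-180 + dlon / 2, 180 - dlon / 2, length.out = nlon)

  # HI: smooth log-spaced longitude gradient with multiplicative jitter
  log_hi_col <- seq(log(config$hi_range[1]), log(config$hi_range[2]),
    length.out = nlon
  )
  hi <- exp(matrix(log_hi_col, nlat, nlon, byrow = TRUE) +
    matrix(stats::rnorm(npix, 0, config$hi_jitter_sd), nlat, nlon))
  hi <- pmin(pmax(hi, config$hi_range[1] / 2), config$hi_range[2] * 2)

  w_pa <- config$w_pa_fn(hi)
  w_par <- config$w_par_fn(hi)
  lag <- matrix(as.integer(config$lag_fn(hi)), nlat, nlon)

  year0 <- 2001L
  year <- rep(year0 + seq_len(config$n_years) - 1L, each = ppy)
  period <- rep(seq_len(ppy), config$n_years)

  a_c <- config$coupling[["a_c"]]
  b_c <- config$coupling[["b_c"]]
  ns <- config$noise_sd
  cfs <- matrix(stats::rnorm(n_t * npix), n_t, npix)
  pa_anom <- a_c * cfs + matrix(stats::rnorm(n_t * npix, 0, ns[["pa"]]), n_t, npix)
  par_anom <- -b_c * cfs + matrix(stats::rnorm(n_t * npix, 0, ns[["par"]]), n_t, npix)
  e3 <- matrix(stats::rnorm(n_t * npix, 0, ns[["gpp"]]), n_t, npix)

  lag_vec <- as.vector(lag)
  pa_lagged <- pa_anom
  for (L in setdiff(unique(lag_vec), 0L)) {
    cols <- which(lag_vec == L)
    pa_lagged[, cols] <- rbind(
      matrix(NA_real_, L, length(cols)),
      pa_anom[seq_len(n_t - L), cols, drop = FALSE]
    )
  }
  gpp_anom <- pa_lagged * rep(as.vector(w_pa), each = n_t) +
    par_anom * rep(as.vector(w_par), each = n_t) + e3

  t2m_anom <- matrix(stats::rnorm(n_t * npix), n_t, npix)
  q_anom <- matrix(stats::rnorm(n_t * npix), n_t, npix)
  pet_anom <- matrix(stats::rnorm(n_t * npix), n_t, npix)

  # climatological structure tied to HI / latitude
  pa_annual <- 900 * hi / (1 + 0.5 * hi) # mm per year
  pet_annual <- pa_annual / hi
  pa_mean <- as.vector(pa_annual) / ppy # mm per period
  pet_mean <- as.vector(pet_annual) / ppy
  gpp_mean <- as.vector(4 * hi / (0.5 + hi))
  t2m_mean <- rep(27 - 0.45 * abs(lat), times = nlon)

  seas <- .seasonal_shape(period, ppy, lat) # [n_t, nlat]
  seas_pix <- seas[, rep(seq_len(nlat), times = nlon)] # [n_t, npix]
  yr_off <- year - year0

  scales <- list(
    cf = 0.08, pa = 0.2 * pa_mean, par = 15, t2m = 1.5, q = 5e-4,
    gpp = 0.2 * gpp_mean, pet = 0.15 * pet_mean
  )
  tr <- config$trend_per_year

  build <- function(mean_pix, seas_amp_pix, trend, scale_pix, anom,
                    floor0 = FALSE, cap1 = FALSE) {
    v <- rep(mean_pix, each = 1L) # npix vector
    raw <- matrix(v, n_t, npix, byrow = TRUE) +
      seas_pix * matrix(seas_amp_pix, n_t, npix, byrow = TRUE) +
      outer(yr_off, rep(trend, npix)) +
      anom * matrix(scale_pix, n_t, npix, byrow = TRUE)
    if (floor0) raw <- pmax(raw, 0)
    if (cap1) raw <- pmin(pmax(raw, 0), 1)
    raw
  }

  raw <- list(
    cf = build(rep(0.55, npix), rep(0.1, npix), tr[["cf"]],
      rep(scales$cf, npix), cfs,
      cap1 = TRUE
    ),
    pa = build(pa_mean, 0.4 * pa_mean, tr[["pa"]], scales$pa, pa_anom,
      floor0 = TRUE
    ),
    par = build(rep(120, npix), rep(60, npix), tr[["par"]],
      rep(scales$par, npix), par_anom,
      floor0 = TRUE
    ),
    t2m = build(t2m_mean, rep(8, npix), tr[["t2m"]],
      rep(scales$t2m, npix), t2m_anom
    ),
    q = build(rep(0.008, npix), rep(0.002, npix), tr[["q"]],
      rep(scales$q, npix), q_anom,
      floor0 = TRUE
    ),
    gpp = build(gpp_mean, 0.5 * gpp_mean, tr[["gpp"]], scales$gpp,
      gpp_anom,
      floor0 = TRUE
    ),
    pet = build(pet_mean, 0.4 * pet_mean, tr[["pet"]], scales$pet,
      pet_anom,
      floor0 = TRUE
    )
  )
  if (config$missing_frac > 0) {
    for (v in names(raw)) {
      drop <- stats::runif(n_t * npix) < config$missing_frac
      raw[[v]][drop] <- NA_real_
    }
  }
  units <- c(
    cf = "1", pa = "mm period-1", par = "W m-2", t2m = "degC",
    q = "kg kg-1", gpp = "g C m-2 d-1", pet = "mm period-1"
  )
  fields <- lapply(.world_vars, function(v) {
    gridded_field(array(raw[[v]], c(n_t, nlat, nlon)), lat, lon,
      year, period, .res_of_ppy(ppy),
      name = v, units = units[[v]]
    )
  })
  names(fields) <- .world_vars

  s_true <- w_pa * a_c - w_par * b_c
  scale_gpp <- matrix(scales$gpp, nlat, nlon)
  truth <- list(
    s_true = s_true,
    beta_pa_true = w_pa,
    beta_par_true = w_par,
    lag_true = lag,
    beta_cf_annual_true = s_true * scale_gpp / scales$cf
  )
  anomalies <- lapply(
    list(cf = cfs, pa = pa_anom, par = par_anom, gpp = gpp_anom),
    function(m) array(m, c(n_t, nlat, nlon))
  )
  structure(
    list(
      config = config, lat = lat, lon = lon, year = year,
      period = period, hi_true = hi, fields = fields,
      anomalies = anomalies, scales = scales, truth = truth
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d x %d grid, %d years x %d periods, seed %d\n",
    x$config$n_lat, x$config$n_lon, x$config$n_years,
    x$config$periods_per_year, x$config$seed
  ))
  invisible(x)
}

# ---- site records -----------------------------------------------------

# within-year period index of each (365-calendar) day of year
period_of_doy <- function(resolution) {
  switch(resolution,
    "daily" = 1:365,
    "8-daily" = eightday_of_doy(1:365),
    "monthly" = month_of_doy(1:365)
  )
}

# calendar dates of year y without Feb 29
.dates_of_year <- function(y) {
  d <- seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)),
    by = "day"
  )
  d[format(d, "%m-%d") != "02-29"]
}

#' Derive daily flux-tower-style site records from the world
#'
#' Samples `n_sites` pixels and expands each pixel's series to daily
#' resolution (piecewise-constant across each period, with daily noise
#' added to GPP and precipitation). Incoming shortwave is exactly twice
#' the pixel's photosynthetically active radiation (`SWin = 2 x PAR`).
#' Record lengths are heterogeneous by default — including records
#' shorter than 3 years and longer than 10 — so the site filters and
#' the long-record detrending rule are exercised.
#'
#' @param world a [make_world()] result.
#' @param n_sites number of sites (at most the number of pixels).
#' @param min_years if given, all record spans are forced to at least
#'   this many years.
#' @param seed RNG seed for sampling and daily noise.
#' @return list of [site_record()]s.
#' @export
make_site_records <- function(world, n_sites, min_years = NULL, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  nlat <- world$config$n_lat
  nlon <- world$config$n_lon
  npix <- nlat * nlon
  if (n_sites > npix) stop("n_sites exceeds the number of pixels")
  set.seed(seed)
  pix <- sample.int(npix, n_sites)
  n_years <- world$config$n_years
  spans <- pmin(pmax(2L + stats::rpois(n_sites, 4), 2L), n_years)
  if (n_sites >= 2L && is.null(min_years)) {
    spans[1L] <- 2L # guaranteed short record
    spans[2L] <- min(n_years, 12L) # guaranteed long record
  }
  if (!is.null(min_years)) spans <- pmax(spans, as.integer(min_years))
  pmap <- period_of_doy(world$fields$gpp$resolution)
  years_all <- sort(unique(world$year))
  records <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    i <- (pix[s] - 1L) %% nlat + 1L
    j <- (pix[s] - 1L) %/% nlat + 1L
    span <- spans[s]
    y_start <- years_all[sample.int(n_years - span + 1L, 1L)]
    yrs <- y_start:(y_start + span - 1L)
    sel <- world$year %in% yrs
    per_day <- function(v) {
      series <- field_series(world$fields[[v]], i, j)[sel]
      prd <- world$period[sel]
      yr <- world$year[sel]
      # expand each (year, period) value to its member days
      unlist(lapply(yrs, function(y) {
        vals <- series[yr == y]
        vals[pmap]
      }), use.names = FALSE)
    }
    days_per_period <- tabulate(pmap, nbins = max(pmap))
    n_days <- 365L * span
    par_daily <- per_day("par")
    pa_daily <- per_day("pa") / days_per_period[rep(pmap, span)]
    gpp_daily <- pmax(per_day("gpp") + stats::rnorm(n_days, 0, 0.3), 0)
    pa_daily <- pmax(pa_daily * exp(stats::rnorm(n_days, 0, 0.3)), 0)
    tair <- per_day("t2m") + stats::rnorm(n_days, 0, 1)
    swin <- 2 * par_daily
    le <- pmax(20 + 0.4 * par_daily + stats::rnorm(n_days, 0, 10), 1)
    h <- pmax(5 + 0.25 * par_daily + stats::rnorm(n_days, 0, 10), 1)
    wind <- pmax(2 + stats::rnorm(n_days, 0, 0.8), 0.1)
    vpd <- pmax(6 + 0.4 * tair + stats::rnorm(n_days, 0, 2), 0.1)
    dates <- do.call(c, lapply(yrs, .dates_of_year))
    records[[s]] <- site_record(
      site_id = sprintf("SYN-%03d", s),
      lat = world$lat[i] + stats::runif(1, -0.1, 0.1),
      lon = world$lon[j] + stats::runif(1, -0.1, 0.1),
      data = data.frame(
        date = dates, gpp = gpp_daily, pa = pa_daily, swin = swin,
        tair = tair, wind = wind, le = le, h = h, vpd = vpd
      )
    )
  }
  records
}

# ---- cloud-type joint histograms --------------------------------------

#' Synthetic COT x CTP joint histograms
#'
#' Distributes each pixel/time total cloud fraction over the 8 x 7
#' joint-histogram bins with a smooth unimodal weight whose mode moves
#' toward optically thick, low-top (rain-bearing) categories when the
#' precipitation anomaly is high. Cells are nonnegative and sum exactly
#' to the pixel's total CF; an all-clear pixel yields an all-zero
#' histogram.
#'
#' @param world a [make_world()] result.
#' @param seed unused at present (the weights are deterministic given
#'   the world), kept for interface stability.
#' @return a `cloud_histogram_field`: list with `values`
#'   (`time x lat x lon x 8 x 7` array), bin edges, coordinates and
#'   time axis.
#' @export
make_cloud_histograms <- function(world, seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  cf <- world$fields$cf$values
  d <- dim(cf)
  n <- prod(d)
  pa_anom <- world$anomalies$pa
  cfv <- as.vector(cf)
  pav <- as.vector(pa_anom)
  pav[is.na(pav)] <- 0
  cc <- 4.5 + 2 * tanh(pav) # COT bin index center (1..8)
  cp <- 4 + 2 * tanh(pav) # CTP bin index center (1..7)
  nc <- 8L
  np <- 7L
  w <- matrix(0, n, nc * np)
  for (ci in seq_len(nc)) {
    for (pj in seq_len(np)) {
      w[, (pj - 1L) * nc + ci] <- exp(-((ci - cc)^2 + (pj - cp)^2) / (2 * 1.5^2))
    }
  }
  w <- w / rowSums(w) * cfv
  vals <- array(w, c(d, nc, np))
  structure(
    list(
      values = vals,
      cot_edges = default_cot_edges, ctp_edges = default_ctp_edges,
      lat = world$lat, lon = world$lon,
      year = world$year, period = world$period,
      resolution = world$fields$cf$resolution
    ),
    class = "cloud_histogram_field"
  )
}
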