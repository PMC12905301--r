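# Independent closed-form oracles and fixture builders, kept separate
# from the package's fitting code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# OLS by explicit normal-equation matrix algebra (intercept included)
oracle_ols <- function(y, X) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(y, X)
  y <- y[keep]
  Xf <- cbind(1, X[keep, , drop = FALSE])
  XtX <- t(Xf) %*% Xf
  beta <- solve(XtX, t(Xf) %*% y)
  resid <- y - Xf %*% beta
  n <- length(y)
  k <- ncol(Xf) - 1L
  df <- n - k - 1L
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(sigma2 * solve(XtX)))
  tval <- drop(beta) / se
  list(
    beta = drop(beta), se = se,
    p = 2 * stats::pt(-abs(tval), df),
    r2 = 1 - sum(resid^2) / sum((y - mean(y))^2),
    n = n
  )
}

# VIF by auxiliary-regression R^2, coded independently
oracle_vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) == 1L) {
    return(1)
  }
  vapply(seq_len(ncol(X)), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

# quick single-pixel gridded field around a numeric series
series_field <- function(values, resolution = "8-daily", lat = 45, lon = 10,
                         start_year = 2001L, name = "x", units = "1") {
  ppy <- periods_per_year(resolution)
  n <- length(values)
  stopifnot(n %% ppy == 0 || resolution == "annual")
  ny <- ceiling(n / ppy)
  year <- rep(start_year + seq_len(ny) - 1L, each = ppy)[seq_len(n)]
  period <- rep(seq_len(ppy), ny)[seq_len(n)]
  gridded_field(array(values, c(n, 1L, 1L)), lat, lon, year, period,
    resolution,
    name = name, units = units
  )
}

annual_field <- function(values_by_year, lat, lon, name = "x", units = "1",
                         start_year = 2001L) {
  ny <- dim(values_by_year)[1]
  gridded_field(values_by_year, lat, lon,
    year = start_year + seq_len(ny) - 1L,
    period = rep(1L, ny), resolution = "annual",
    name = name, units = units
  )
}

# Homogeneous-truth annual world with independent drivers, for
# attribution parameter recovery: gpp = b0 + bcf*cf + bt*t2m + bq*q + e.
# Levels are random walks so the year-to-year differences entering the
# regression are iid, matching the estimator's error model.
make_annual_attr_fields <- function(nlat = 10L, nlon = 50L, n_years = 20L,
                                    beta_cf = -2, beta_t2m = 0.5,
                                    beta_q = 100, noise_sd = 0.1,
                                    seed = 1L) {
  set.seed(seed)
  lat <- seq(-45, 45, length.out = nlat)
  lon <- seq(-180 + 360 / nlon / 2, 180 - 360 / nlon / 2, length.out = nlon)
  n <- n_years * nlat * nlon
  walk <- function(level, sd) {
    innov <- array(stats::rnorm(n, 0, sd), c(n_years, nlat, nlon))
    level + apply(innov, c(2, 3), cumsum)
  }
  cf <- walk(0.5, 0.05)
  t2m <- walk(15, 0.8)
  q <- walk(0.008, 0.002)
  gpp <- 3 + beta_cf * cf + beta_t2m * t2m + beta_q * q +
    walk(0, noise_sd)
  list(
    gpp = annual_field(gpp, lat, lon, "gpp"),
    cf = annual_field(cf, lat, lon, "cf"),
    t2m = annual_field(t2m, lat, lon, "t2m"),
    q = annual_field(q, lat, lon, "q"),
    truth = c(cf = beta_cf, t2m = beta_t2m, q = beta_q)
  )
}

# generator-style arid-pixel anomaly series with a pure lag on the
# precipitation channel
arid_pixel_series <- function(n = 920L, lag = 3L, w_pa = 0.65,
                              w_par = 0.05, a_c = 0.7, b_c = 0.7,
                              noise = c(0.5, 0.5, 0.5)) {
  cf <- stats::rnorm(n)
  pa <- a_c * cf + stats::rnorm(n, 0, noise[1])
  par <- -b_c * cf + stats::rnorm(n, 0, noise[2])
  pa_l <- if (lag > 0) c(rep(NA_real_, lag), pa[seq_len(n - lag)]) else pa
  gpp <- w_pa * pa_l + w_par * par + stats::rnorm(n, 0, noise[3])
  list(cf = cf, pa = pa, par = par, gpp = gpp)
}
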