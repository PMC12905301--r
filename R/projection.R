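# Projection of cloud-driven GPP change: CF anomalies relative to a
# five-year baseline, their product with the annual-scale sensitivity,
# linear trends with Student's-t significance, and cosine-latitude
# area-weighted regional series with 99% confidence intervals.

#' CF change relative to the initial-years baseline
#'
#' `dCF_y = CF_y - mean(CF over the first baseline_years)`, per pixel;
#' the baseline-window mean of the result is zero by construction.
#'
#' @param cf_annual annual [gridded_field()] of CF.
#' @param baseline_years number of initial years in the baseline
#'   (default 5).
#' @return an annual [gridded_field()] of changes.
#' @export
cf_change_series <- function(cf_annual, baseline_years = 5L) {
  stopifnot(inherits(cf_annual, "gridded_field"))
  if (cf_annual$resolution != "annual") {
    stop("cf_change_series expects an annual field")
  }
  ny <- dim(cf_annual$values)[1]
  if (ny < baseline_years) {
    stop("record is shorter than the baseline window")
  }
  base <- apply(
    cf_annual$values[seq_len(baseline_years), , , drop = FALSE],
    c(2, 3), mean
  )
  d <- sweep(cf_annual$values, c(2, 3), base, "-")
  field_like(cf_annual, d, name = paste0("delta_", cf_annual$name))
}

#' CF-driven GPP change
#'
#' `dGPP_CF = beta_CF x dCF`, elementwise. When the sensitivity layer
#' lives on a different grid, supply its coordinates and it is
#' bilinearly interpolated to the CF grid first.
#'
#' @param beta_cf `lat x lon` matrix of annual GPP-to-CF sensitivity
#'   (g C m-2 d-1 per unit CF).
#' @param dcf annual [gridded_field()] of CF changes
#'   (from [cf_change_series()]).
#' @param beta_lat,beta_lon coordinates of `beta_cf` if its grid
#'   differs from `dcf`'s.
#' @return an annual [gridded_field()] of GPP changes.
#' @export
gpp_change_from_cf <- function(beta_cf, dcf, beta_lat = NULL,
                               beta_lon = NULL) {
  stopifnot(inherits(dcf, "gridded_field"))
  target_dim <- dim(dcf$values)[2:3]
  if (!identical(dim(beta_cf), as.integer(target_dim))) {
    if (is.null(beta_lat) || is.null(beta_lon)) {
      stop(
        "beta_cf grid does not match the CF grid; supply beta_lat/",
        "beta_lon for bilinear regridding"
      )
    }
    bf <- gridded_field(
      array(beta_cf, c(1L, length(beta_lat), length(beta_lon))),
      beta_lat, beta_lon,
      year = dcf$year[1], period = 1L, resolution = "annual",
      name = "beta_cf", units = "g C m-2 d-1"
    )
    bre <- regrid_bilinear(bf, grid_spec(dcf$lat, dcf$lon))
    beta_cf <- bre$values[1, , ]
  }
  out <- sweep(dcf$values, c(2, 3), beta_cf, "*")
  field_like(dcf, out, name = "delta_gpp_cf", units = "g C m-2 d-1")
}

#' Linear trend of an annual series
#'
#' OLS slope on the (mean-centred) year index with a two-sided
#' Student's t P-value.
#'
#' @param series numeric annual values.
#' @param years year labels (default: index).
#' @return a `trend_estimate`: list with `gamma` (units per year),
#'   `p_value`, `stderr`, `n_years`.
#' @export
linear_trend <- function(series, years = seq_along(series)) {
  keep <- !is.na(series) & !is.na(years)
  y <- series[keep]
  t <- years[keep]
  if (length(y) < 3L) stop("at least three years are required for a trend")
  tc <- t - mean(t)
  sxx <- sum(tc^2)
  gamma <- sum(tc * y) / sxx
  resid <- y - mean(y) - gamma * tc
  df <- length(y) - 2L
  se <- sqrt(sum(resid^2) / df / sxx)
  p <- if (se > 0) {
    2 * stats::pt(abs(gamma / se), df, lower.tail = FALSE)
  } else if (gamma != 0) {
    0
  } else {
    NA_real_
  }
  structure(
    list(gamma = gamma, p_value = p, stderr = se, n_years = length(y)),
    class = "trend_estimate"
  )
}

#' Per-pixel linear trend of an annual field
#'
#' @param field annual [gridded_field()].
#' @param min_years minimum valid years per pixel (default 3).
#' @return list of matrices `gamma` and `p_value`.
#' @export
trend_map <- function(field, min_years = 3L) {
  stopifnot(field$resolution == "annual")
  nlat <- length(field$lat)
  nlon <- length(field$lon)
  g <- p <- matrix(NA_real_, nlat, nlon)
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      v <- field_series(field, i, j)
      if (sum(!is.na(v)) < min_years) next
      tr <- linear_trend(v, field$year)
      g[i, j] <- tr$gamma
      p[i, j] <- tr$p_value
    }
  }
  list(gamma = g, p_value = p)
}

#' CF-trend-driven GPP trend
#'
#' `gammaGPP_CF = beta_CF x gammaCF`, elementwise.
#'
#' @param beta_cf sensitivity matrix.
#' @param gamma_cf CF trend matrix (per year).
#' @return matrix of GPP trends (g C m-2 d-1 per year).
#' @export
gpp_trend_from_cf <- function(beta_cf, gamma_cf) {
  stopifnot(identical(dim(beta_cf), dim(gamma_cf)))
  beta_cf * gamma_cf
}

#' Area-weighted regional mean series with 99% confidence interval
#'
#' Cosine-latitude weighted mean over the masked pixels at each time
#' step. The confidence interval is the normal 99% half-width of the
#' weighted mean treating pixels as the sampling units:
#' `ci99 = qnorm(0.995) * sd_w * sqrt(sum(w^2)) / sum(w)`, where `sd_w`
#' is the weighted spatial standard deviation — i.e. spatial spread,
#' not temporal bootstrap.
#'
#' @param field a [gridded_field()].
#' @param mask logical `lat x lon` matrix of pixels to include
#'   (default: all).
#' @return data.frame with `year`, `period`, `mean`, `ci99`, `n`.
#' @export
area_weighted_mean <- function(field, mask = NULL) {
  nlat <- length(field$lat)
  nlon <- length(field$lon)
  if (is.null(mask)) mask <- matrix(TRUE, nlat, nlon)
  if (!any(mask, na.rm = TRUE)) stop("mask selects no pixels")
  w_full <- matrix(cos(field$lat * pi / 180), nlat, nlon)
  w_full[!mask | is.na(mask)] <- NA_real_
  nt <- dim(field$values)[1]
  mean_v <- ci_v <- rep(NA_real_, nt)
  n_v <- integer(nt)
  z99 <- stats::qnorm(0.995)
  for (t in seq_len(nt)) {
    x <- field$values[t, , ]
    ok <- !is.na(x) & !is.na(w_full)
    n <- sum(ok)
    n_v[t] <- n
    if (n == 0L) next
    w <- w_full[ok]
    xv <- x[ok]
    m <- sum(w * xv) / sum(w)
    mean_v[t] <- m
    if (n >= 2L) {
      var_w <- sum(w * (xv - m)^2) / sum(w) * n / (n - 1)
      ci_v[t] <- z99 * sqrt(var_w) * sqrt(sum(w^2)) / sum(w)
    } else {
      ci_v[t] <- 0
    }
  }
  data.frame(
    year = field$year, period = field$period,
    mean = mean_v, ci99 = ci_v, n = n_v
  )
}

#' Regional projection series for global / arid / humid vegetation
#'
#' Convenience wrapper producing the three area-weighted series used
#' in regional summaries: all vegetated pixels, arid (`HI < 1`) and
#' humid (`HI > 1`).
#'
#' @param field a [gridded_field()] (e.g. CF-driven GPP change).
#' @param hi humidity-index matrix.
#' @param veg_mask logical vegetation mask (default: all pixels).
#' @return data.frame with columns `region`, `year`, `mean`, `ci99`,
#'   `n`.
#' @export
regional_series <- function(field, hi, veg_mask = NULL) {
  nlat <- length(field$lat)
  nlon <- length(field$lon)
  if (is.null(veg_mask)) veg_mask <- matrix(TRUE, nlat, nlon)
  masks <- list(
    global = veg_mask,
    arid = veg_mask & !is.na(hi) & hi < 1,
    humid = veg_mask & !is.na(hi) & hi > 1
  )
  out <- lapply(names(masks), function(nm) {
    df <- area_weighted_mean(field, masks[[nm]])
    df$region <- nm
    df
  })
  do.call(rbind, out)[, c("region", "year", "period", "mean", "ci99", "n")]
}
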