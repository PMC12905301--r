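# Anomaly standardization and spatial/temporal harmonization.
#
# Standardization is a two-step, per-calendar-period contract: an
# interannual linear trend is removed for each calendar day/period
# separately (X'_t = X_t - (a t + b)), then the residuals are Z-scored
# across years for the same calendar period (X* = (X' - mu) / sigma).
# After both steps every calendar period has cross-year mean 0 and sd 1
# wherever enough valid years exist.

# ---- calendar helpers -------------------------------------------------

# cumulative day counts for a fixed 365-day year (Feb 29 dropped)
.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_ends <- cumsum(.month_days)

# day-of-year (1..365) -> month (1..12)
month_of_doy <- function(doy) {
  findInterval(doy - 1L, c(0L, .month_ends[-12L])) |> as.integer()
}

# day-of-year -> 8-daily period (1..46), periods restart each Jan 1
eightday_of_doy <- function(doy) {
  as.integer((doy - 1L) %/% 8L + 1L)
}

# source period index -> target period index, for one resolution pair
period_mapping <- function(from, to) {
  if (to == "annual") {
    return(rep(1L, periods_per_year(from)))
  }
  if (from == "daily" && to == "8-daily") {
    return(eightday_of_doy(1:365))
  }
  if (from == "daily" && to == "monthly") {
    return(month_of_doy(1:365))
  }
  if (from == "8-daily" && to == "monthly") {
    # assign each 8-day period to the month containing its middle day
    start <- (0:45) * 8L + 1L
    mid <- pmin(start + 3L, 365L)
    return(month_of_doy(mid))
  }
  stop(sprintf("unsupported composite: %s -> %s", from, to))
}

.res_order <- c("daily" = 1L, "8-daily" = 2L, "monthly" = 3L, "annual" = 4L)

# ---- detrending (per calendar period across years) --------------------

#' Remove the interannual linear trend per calendar period
#'
#' For every pixel and calendar period (day, 8-day period or month), an
#' OLS line is fitted to the values of that period across years, and the
#' residuals replace the values. Pixels whose valid record spans fewer
#' than `min_years_detrend` years are returned unchanged (with the
#' per-pixel `detrended_flag` set to `FALSE`) — the rule applied to
#' short flux-tower records; gridded multi-decadal inputs use
#' `min_years_detrend = 0` so they are always detrended.
#'
#' Calendar periods with fewer than 2 valid years cannot be fit and
#' become missing.
#'
#' @param field a [gridded_field()] at daily, 8-daily or monthly
#'   resolution (annual input is rejected: use [year_to_year_deltas()]
#'   for annual series).
#' @param min_years_detrend minimum record span (years) required before
#'   detrending is applied; shorter records pass through unchanged.
#' @return a `detrended_field` (a [gridded_field()] carrying per-period
#'   trend coefficients in `$trend_fit` and a per-pixel
#'   `$detrended_flag` matrix).
#' @export
detrend_calendar <- function(field, min_years_detrend = 0) {
  stopifnot(inherits(field, "gridded_field"))
  if (field$resolution == "annual") {
    stop(
      "calendar-period detrending is undefined at annual resolution; ",
      "use year_to_year_deltas() for annual series"
    )
  }
  ppy <- periods_per_year(field$resolution)
  dims <- dim(field$values)
  n_t <- dims[1]
  npix <- dims[2] * dims[3]
  vals <- matrix(field$values, n_t, npix)

  # per-pixel record span in years (valid data only)
  has_valid <- !is.na(vals)
  span <- apply(has_valid, 2, function(v) {
    yr <- field$year[v]
    if (!length(yr)) 0L else diff(range(yr)) + 1L
  })
  detrend_pix <- span >= max(min_years_detrend, 0)

  out <- vals
  a_arr <- array(NA_real_, c(ppy, npix))
  b_arr <- array(NA_real_, c(ppy, npix))
  for (p in sort(unique(field$period))) {
    idx <- which(field$period == p)
    yr <- as.numeric(field$year[idx])
    Y <- vals[idx, , drop = FALSE]
    M <- !is.na(Y)
    n <- colSums(M)
    tM <- yr * M
    St <- colSums(tM)
    Stt <- colSums(yr^2 * M)
    Y0 <- Y
    Y0[!M] <- 0
    Sx <- colSums(Y0)
    Stx <- colSums(yr * Y0)
    den <- n * Stt - St^2
    a <- ifelse(n >= 2 & den > 0, (n * Stx - St * Sx) / den, NA_real_)
    b <- ifelse(n >= 2 & den > 0, (Sx - a * St) / n, NA_real_)
    fitted <- outer(yr, a) + rep(b, each = length(idx))
    resid <- Y - fitted
    # too few years to fit -> missing
    resid[, is.na(a)] <- NA_real_
    # short-record pixels keep raw values, recorded as a zero trend
    resid[, !detrend_pix] <- Y[, !detrend_pix]
    a[!detrend_pix] <- 0
    b[!detrend_pix] <- 0
    out[idx, ] <- resid
    a_arr[p, ] <- a
    b_arr[p, ] <- b
  }
  res <- field_like(field, array(out, dims))
  res$trend_fit <- list(
    a = array(a_arr, c(ppy, dims[2], dims[3])),
    b = array(b_arr, c(ppy, dims[2], dims[3]))
  )
  res$detrended_flag <- matrix(detrend_pix, dims[2], dims[3])
  class(res) <- c("detrended_field", class(res))
  res
}

# ---- Z-scoring (per calendar period across years) ---------------------

#' Z-score per calendar period across years
#'
#' Removes the seasonal cycle by standardizing each calendar period
#' across years: `X* = (X' - mu) / sigma`, where `mu` and `sigma` are
#' the cross-year mean and standard deviation of the (detrended) values
#' for that period. Values become missing where fewer than
#' `min_valid_years` years are valid or where `sigma` is zero.
#'
#' @param field a `detrended_field` from [detrend_calendar()], or any
#'   [gridded_field()] with `skip_detrend = TRUE` (e.g. to standardize a
#'   field that is already an anomaly).
#' @param min_valid_years minimum valid years per calendar period
#'   (default 3; a 2-point standard deviation carries no information).
#' @param skip_detrend allow input that has not been detrended.
#' @return a `standardized_field`: a [gridded_field()] whose values are
#'   `X*`, carrying `$fit` (per-period `a`, `b`, `mu`, `sigma` arrays)
#'   and the per-pixel `$detrended_flag`.
#' @export
zscore_calendar <- function(field, min_valid_years = 3, skip_detrend = FALSE) {
  stopifnot(inherits(field, "gridded_field"))
  if (!inherits(field, "detrended_field") && !skip_detrend) {
    stop(
      "input has not been detrended; call detrend_calendar() first ",
      "or pass skip_detrend = TRUE"
    )
  }
  ppy <- periods_per_year(field$resolution)
  dims <- dim(field$values)
  n_t <- dims[1]
  npix <- dims[2] * dims[3]
  vals <- matrix(field$values, n_t, npix)
  out <- matrix(NA_real_, n_t, npix)
  mu_arr <- array(NA_real_, c(ppy, npix))
  sd_arr <- array(NA_real_, c(ppy, npix))
  for (p in sort(unique(field$period))) {
    idx <- which(field$period == p)
    Y <- vals[idx, , drop = FALSE]
    M <- !is.na(Y)
    n <- colSums(M)
    Y0 <- Y
    Y0[!M] <- 0
    mu <- ifelse(n > 0, colSums(Y0) / n, NA_real_)
    dev <- (Y - rep(mu, each = length(idx)))^2
    dev[!M] <- 0
    sigma <- ifelse(n >= 2, sqrt(colSums(dev) / pmax(n - 1, 1)), NA_real_)
    ok <- n >= min_valid_years & !is.na(sigma) & sigma > 0
    z <- (Y - rep(mu, each = length(idx))) / rep(sigma, each = length(idx))
    z[, !ok] <- NA_real_
    out[idx, ] <- z
    mu[!ok] <- ifelse(n[!ok] > 0, mu[!ok], NA_real_)
    mu_arr[p, ] <- mu
    sigma[!ok] <- NA_real_
    sd_arr[p, ] <- sigma
  }
  res <- field_like(field, array(out, dims))
  tf <- field$trend_fit %||% list(
    a = array(NA_real_, c(ppy, dims[2], dims[3])),
    b = array(NA_real_, c(ppy, dims[2], dims[3]))
  )
  res$fit <- list(
    a = tf$a, b = tf$b,
    mu = array(mu_arr, c(ppy, dims[2], dims[3])),
    sigma = array(sd_arr, c(ppy, dims[2], dims[3]))
  )
  res$detrended_flag <- field$detrended_flag %||%
    matrix(inherits(field, "detrended_field"), dims[2], dims[3])
  class(res) <- c("standardized_field", "gridded_field")
  res
}

#' Standardize a field (detrend + Z-score) in one call
#'
#' @inheritParams detrend_calendar
#' @inheritParams zscore_calendar
#' @return a `standardized_field`, see [zscore_calendar()].
#' @export
standardize_field <- function(field, min_years_detrend = 0,
                              min_valid_years = 3) {
  zscore_calendar(detrend_calendar(field, min_years_detrend),
    min_valid_years = min_valid_years
  )
}

# ---- temporal compositing ---------------------------------------------

#' Composite a field to a coarser temporal resolution
#'
#' Averages source steps falling into each target calendar period
#' (8-daily periods restart each Jan 1; the 46th period is short). A
#' target period is missing when fewer than `min_valid_frac` of its
#' member source steps (those present on the input time axis) are
#' valid.
#'
#' @param field a [gridded_field()].
#' @param target target resolution, coarser than the source.
#' @param min_valid_frac minimum valid fraction of member steps
#'   (default 0.5).
#' @return a [gridded_field()] at the target resolution.
#' @export
temporal_composite <- function(field, target, min_valid_frac = 0.5) {
  stopifnot(inherits(field, "gridded_field"))
  target <- match.arg(target, c("8-daily", "monthly", "annual"))
  if (.res_order[[target]] <= .res_order[[field$resolution]]) {
    stop(sprintf(
      "target resolution (%s) must be coarser than source (%s)",
      target, field$resolution
    ))
  }
  pm <- period_mapping(field$resolution, target)
  tgt_period <- pm[field$period]
  key <- field$year * 1000L + tgt_period
  groups <- split(seq_along(key), key)
  dims <- dim(field$values)
  npix <- dims[2] * dims[3]
  vals <- matrix(field$values, dims[1], npix)
  keys <- as.integer(names(groups))
  ord <- order(keys)
  groups <- groups[ord]
  keys <- keys[ord]
  out <- matrix(NA_real_, length(groups), npix)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    Y <- vals[idx, , drop = FALSE]
    M <- !is.na(Y)
    nvalid <- colSums(M)
    Y0 <- Y
    Y0[!M] <- 0
    m <- colSums(Y0) / nvalid
    m[nvalid < min_valid_frac * length(idx)] <- NA_real_
    out[g, ] <- m
  }
  gridded_field(array(out, c(length(groups), dims[2], dims[3])),
    field$lat, field$lon,
    year = keys %/% 1000L, period = keys %% 1000L,
    resolution = target, name = field$name, units = field$units
  )
}

# ---- regridding -------------------------------------------------------

#' Define a regular lat/lon grid
#'
#' @param lat,lon strictly increasing cell-center coordinates (degrees).
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(lat, lon) {
  stopifnot(all(diff(lat) > 0), all(diff(lon) > 0))
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon)),
    class = "grid_spec"
  )
}

# cell edges from centers (midpoints, extended half a step at the ends)
.cell_edges <- function(centers) {
  if (length(centers) == 1L) {
    return(c(centers - 0.5, centers + 0.5))
  }
  mid <- (centers[-1] + centers[-length(centers)]) / 2
  step1 <- centers[2] - centers[1]
  stepn <- centers[length(centers)] - centers[length(centers) - 1]
  c(centers[1] - step1 / 2, mid, centers[length(centers)] + stepn / 2)
}

#' Box-mean regridding (fine to coarse)
#'
#' Each target cell takes the cosine-latitude-weighted mean of all
#' source cells whose centers fall inside it (half-open cell intervals
#' `[edge_lo, edge_hi)`). A target cell is missing at a time step when
#' fewer than `min_valid_frac` of its member source cells are valid.
#' Cosine weighting makes the regridding conserve the area-weighted
#' global mean of a fully valid field.
#'
#' @param field a [gridded_field()].
#' @param target a [grid_spec()].
#' @param min_valid_frac minimum valid member fraction (default 0.5).
#' @return a [gridded_field()] on the target grid.
#' @export
regrid_box_mean <- function(field, target, min_valid_frac = 0.5) {
  stopifnot(inherits(field, "gridded_field"), inherits(target, "grid_spec"))
  lat_bin <- findInterval(field$lat, .cell_edges(target$lat),
    rightmost.closed = FALSE
  )
  lon_bin <- findInterval(field$lon, .cell_edges(target$lon),
    rightmost.closed = FALSE
  )
  lat_bin[lat_bin < 1 | lat_bin > length(target$lat)] <- NA
  lon_bin[lon_bin < 1 | lon_bin > length(target$lon)] <- NA
  if (all(is.na(lat_bin)) || all(is.na(lon_bin))) {
    stop("no source cell centers fall inside the target grid")
  }
  dims <- dim(field$values)
  nt <- dims[1]
  w_lat <- cos(field$lat * pi / 180)
  out <- array(NA_real_, c(nt, length(target$lat), length(target$lon)))
  for (bi in sort(unique(stats::na.omit(lat_bin)))) {
    ii <- which(lat_bin == bi)
    for (bj in sort(unique(stats::na.omit(lon_bin)))) {
      jj <- which(lon_bin == bj)
      block <- field$values[, ii, jj, drop = FALSE]
      w <- rep(w_lat[ii], times = length(jj))
      bm <- matrix(block, nt, length(ii) * length(jj))
      M <- !is.na(bm)
      wm <- M * rep(w, each = nt)
      bm0 <- bm
      bm0[!M] <- 0
      wsum <- rowSums(wm)
      val <- rowSums(bm0 * rep(w, each = nt)) / wsum
      val[rowSums(M) < min_valid_frac * ncol(bm)] <- NA_real_
      out[, bi, bj] <- val
    }
  }
  gridded_field(out, target$lat, target$lon, field$year, field$period,
    field$resolution,
    name = field$name, units = field$units
  )
}

#' Bilinear regridding
#'
#' Interpolates each time slice bilinearly to the target cell centers
#' (via [pracma::interp2()]). Target coordinates outside the source
#' center hull are clamped to the hull edge (nearest-edge extension),
#' so a common-grid interpolation never produces out-of-domain gaps.
#'
#' @inheritParams regrid_box_mean
#' @return a [gridded_field()] on the target grid.
#' @export
regrid_bilinear <- function(field, target) {
  stopifnot(inherits(field, "gridded_field"), inherits(target, "grid_spec"))
  src_lat <- field$lat
  src_lon <- field$lon
  flip <- FALSE
  if (length(src_lat) > 1 && src_lat[1] > src_lat[2]) {
    src_lat <- rev(src_lat)
    flip <- TRUE
  }
  tl <- pmin(pmax(target$lat, min(src_lat)), max(src_lat))
  tn <- pmin(pmax(target$lon, min(src_lon)), max(src_lon))
  pts <- expand.grid(lat = tl, lon = tn)
  dims <- dim(field$values)
  out <- array(NA_real_, c(dims[1], length(target$lat), length(target$lon)))
  for (t in seq_len(dims[1])) {
    Z <- field$values[t, , , drop = TRUE]
    if (is.null(dim(Z))) Z <- matrix(Z, length(field$lat), length(field$lon))
    if (flip) Z <- Z[rev(seq_len(nrow(Z))), , drop = FALSE]
    if (length(src_lat) == 1L || length(src_lon) == 1L) {
      out[t, , ] <- Z[1, 1] # degenerate single-line grid
      next
    }
    zi <- pracma::interp2(
      x = src_lon, y = src_lat, Z = Z,
      xp = pts$lon, yp = pts$lat, method = "linear"
    )
    out[t, , ] <- matrix(zi, length(target$lat), length(target$lon))
  }
  gridded_field(out, target$lat, target$lon, field$year, field$period,
    field$resolution,
    name = field$name, units = field$units
  )
}

# ---- site records -----------------------------------------------------

#' Construct a site record
#'
#' A daily flux-tower-style record: GPP plus the meteorological columns
#' needed for Penman-Monteith potential evapotranspiration.
#'
#' @param site_id character identifier.
#' @param lat,lon site coordinates (degrees).
#' @param data data.frame with columns `date` (Date), `gpp`
#'   (g C m-2 d-1), `pa` (mm d-1), `swin` (W m-2), `tair` (deg C),
#'   `wind` (m s-1), `le`, `h` (W m-2), `vpd` (hPa).
#' @return a `site_record`.
#' @export
site_record <- function(site_id, lat, lon, data) {
  needed <- c("date", "gpp", "pa", "swin", "tair", "wind", "le", "h", "vpd")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("site record is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(data) < 1L) stop("site record must span at least one day")
  structure(list(site_id = site_id, lat = lat, lon = lon, data = data),
    class = "site_record"
  )
}

#' Record span in years
#'
#' Inclusive day span divided by 365 — the length of the fixed
#' (Feb-29-free) calendar year the pipeline uses, so an N-calendar-year
#' record spans at least N.
#'
#' @param record a [site_record()].
#' @return numeric span in years.
#' @export
site_span_years <- function(record) {
  as.numeric(diff(range(record$data$date)) + 1) / 365
}

#' Filter site records by span and productivity
#'
#' Keeps records with a span of at least `min_span_years` years and a
#' whole-record mean GPP strictly above `min_mean_gpp`.
#'
#' @param records list of [site_record()]s.
#' @param min_span_years minimum record span (default 3 years).
#' @param min_mean_gpp minimum mean GPP (default 0.1 g C m-2 d-1,
#'   strict).
#' @return the retained sublist.
#' @export
filter_sites <- function(records, min_span_years = 3, min_mean_gpp = 0.1) {
  keep <- vapply(records, function(r) {
    site_span_years(r) >= min_span_years &&
      mean(r$data$gpp, na.rm = TRUE) > min_mean_gpp
  }, logical(1))
  records[keep]
}

#' Vegetation mask from multi-year mean GPP
#'
#' @param gpp a [gridded_field()] of GPP.
#' @param threshold mean-GPP threshold (strictly "over"; default
#'   0.1 g C m-2 d-1).
#' @return logical `lat x lon` matrix.
#' @export
vegetation_mask <- function(gpp, threshold = 0.1) {
  m <- map_pixels(gpp, function(v) mean(v, na.rm = TRUE))
  !is.na(m) & m > threshold
}

#' Match a site to its nearest grid cell
#'
#' Minimizes great-circle distance between the site and cell centers;
#' exact ties are broken deterministically (lower `|lat|`, then lower
#' `lon`).
#'
#' @param site a [site_record()] (or any list with `lat`/`lon`).
#' @param field a [gridded_field()].
#' @return list with `lat_index`, `lon_index`, `lat`, `lon` and the
#'   cell's time `series`.
#' @export
match_nearest_grid <- function(site, field) {
  le <- .cell_edges(sort(field$lat))
  ne <- .cell_edges(sort(field$lon))
  if (site$lat < min(le) || site$lat > max(le) ||
    site$lon < min(ne) || site$lon > max(ne)) {
    stop("site lies outside the grid domain")
  }
  g <- expand.grid(i = seq_along(field$lat), j = seq_along(field$lon))
  d <- geosphere::distHaversine(
    cbind(site$lon, site$lat),
    cbind(field$lon[g$j], field$lat[g$i])
  )
  dmin <- min(d)
  cand <- which(d <= dmin * (1 + 1e-12))
  if (length(cand) > 1L) {
    ord <- order(abs(field$lat[g$i[cand]]), field$lon[g$j[cand]])
    cand <- cand[ord[1]]
  }
  i <- g$i[cand]
  j <- g$j[cand]
  list(
    lat_index = i, lon_index = j,
    lat = field$lat[i], lon = field$lon[j],
    series = field_series(field, i, j)
  )
}

# ---- cloud-property derivations ---------------------------------------

#' Grid-mean cloud optical thickness
#'
#' All-sky optical thickness: `COTbar = CF x COT_cloudy`, combining
#' cloudy and clear parts of the cell.
#'
#' @param cf cloud-fraction [gridded_field()] (0-1).
#' @param cot_cloudy mean optical thickness over cloudy pixels only.
#' @return a [gridded_field()] of grid-mean COT.
#' @export
grid_mean_cot <- function(cf, cot_cloudy) {
  stopifnot_aligned(cf, cot_cloudy)
  rng <- range(cf$values, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("cloud fraction must lie in [0, 1]")
  field_like(cf, cf$values * cot_cloudy$values,
    name = "cot_mean", units = cot_cloudy$units
  )
}

#' Night-to-day vegetation optical depth ratio
#'
#' `VODndr = VOD_night / VOD_day`; missing where the daytime value is
#' missing or non-positive.
#'
#' @param vod_night,vod_day aligned [gridded_field()]s.
#' @return a [gridded_field()].
#' @export
vod_night_day_ratio <- function(vod_night, vod_day) {
  stopifnot_aligned(vod_night, vod_day)
  den <- vod_day$values
  den[!is.na(den) & den <= 0] <- NA_real_
  field_like(vod_night, vod_night$values / den,
    name = "vod_ndr", units = "1"
  )
}

# ---- ISCCP cloud-type reclassification --------------------------------

#' Default joint-histogram bin edges (COT x CTP)
#'
#' Eight cloud-optical-thickness bins and seven cloud-top-pressure bins,
#' the layout of satellite COT/CTP joint histograms.
#' @name isccp_bins
#' @export
default_cot_edges <- c(0, 0.3, 1.3, 3.6, 9.4, 23, 60, 100, 150)

#' @rdname isccp_bins
#' @export
default_ctp_edges <- c(0, 180, 310, 440, 560, 680, 800, 1100)

.isccp_classes <- c(
  "cumulus", "stratocumulus", "stratus",
  "altocumulus", "altostratus", "nimbostratus",
  "cirrus", "cirrostratus", "deep_convection"
)

# class index (1..3) for each original bin, or stop() on a straddle
.class_of_bins <- function(edges, class_edges, what) {
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  cl_lo <- class_edges[-length(class_edges)]
  cl_hi <- class_edges[-1]
  idx <- integer(length(lo))
  for (b in seq_along(lo)) {
    inside <- which(lo[b] >= cl_lo - 1e-9 & hi[b] <= cl_hi + 1e-9)
    if (!length(inside)) {
      stop(sprintf(
        "%s bin [%g, %g] straddles a class boundary and cannot be split",
        what, lo[b], hi[b]
      ))
    }
    idx[b] <- inside[1]
  }
  idx
}

#' Reclassify a COT x CTP joint histogram into the nine ISCCP types
#'
#' Sums the original 8 x 7 (COT x CTP) histogram cells into the 3 x 3
#' ISCCP classes — cumulus, stratocumulus, stratus (low, cloud-top
#' pressure 1100-680 hPa); altocumulus, altostratus, nimbostratus (mid,
#' 680-440 hPa); cirrus, cirrostratus, deep convection (high,
#' 440-0 hPa) — split at optical thickness 0 / 3.6 / 23 / 150. The
#' total cloud fraction is conserved. Bin edges that straddle a class
#' boundary are rejected (a bin cannot be split).
#'
#' @param hist numeric matrix `length(cot_edges)-1` x
#'   `length(ctp_edges)-1` of per-bin cloud fractions, or an array whose
#'   last two dimensions are the histogram (e.g. `time x lat x lon x
#'   cot x ctp` from [make_cloud_histograms()]).
#' @param cot_edges,ctp_edges ascending original bin edges.
#' @return for a matrix input, a named 9-vector of class cloud
#'   fractions; for an array, an array with the two histogram
#'   dimensions replaced by one class dimension of length 9.
#' @export
reclassify_isccp <- function(hist, cot_edges = default_cot_edges,
                             ctp_edges = default_ctp_edges) {
  cot_cls <- .class_of_bins(cot_edges, c(0, 3.6, 23, 150), "COT")
  # CTP classes ordered low (1100-680), mid (680-440), high (440-0):
  # ascending-pressure bins map to class 3 - interval + 1
  ctp_cls <- 4L - .class_of_bins(ctp_edges, c(0, 440, 680, 1100), "CTP")
  class_of_cell <- function(ci, pj) (ctp_cls[pj] - 1L) * 3L + cot_cls[ci]

  d <- dim(hist)
  nc <- length(cot_edges) - 1L
  np <- length(ctp_edges) - 1L
  nd <- length(d)
  stopifnot(d[nd - 1L] == nc, d[nd] == np)
  lead <- if (nd > 2L) prod(d[seq_len(nd - 2L)]) else 1L
  hm <- matrix(hist, lead, nc * np)
  out <- matrix(0, lead, 9L)
  for (ci in seq_len(nc)) {
    for (pj in seq_len(np)) {
      k <- class_of_cell(ci, pj)
      out[, k] <- out[, k] + hm[, (pj - 1L) * nc + ci]
    }
  }
  if (nd == 2L) {
    return(stats::setNames(as.numeric(out), .isccp_classes))
  }
  res <- array(out, c(d[seq_len(nd - 2L)], 9L))
  dimnames(res) <- c(
    rep(list(NULL), nd - 2L),
    list(.isccp_classes)
  )
  res
}
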