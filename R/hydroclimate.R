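# Humidity index, Penman-Monteith potential evapotranspiration, and
# the meteorological active season.

#' Humidity index from monthly precipitation and PET
#'
#' `HI = (long-term mean annual PA) / (long-term mean annual PET)` —
#' the ratio of multi-year means, not the mean of yearly ratios. Cells
#' with `HI < 1` are water-limited ("arid"), `HI > 1` energy-limited
#' ("humid"); the exact boundary belongs to neither strict class.
#'
#' @param pa,pet aligned monthly [gridded_field()]s (mm per month).
#' @return a `hydroclimate_field`: list with `hi`, `pa_annual`,
#'   `pet_annual` (mm per year) and `aridity_class` matrices plus
#'   `lat`/`lon`.
#' @export
humidity_index <- function(pa, pet) {
  stopifnot_aligned(pa, pet)
  if (pa$resolution != "monthly") stop("humidity_index expects monthly fields")
  pa_ann <- 12 * map_pixels(pa, function(v) mean(v, na.rm = TRUE))
  pet_ann <- 12 * map_pixels(pet, function(v) mean(v, na.rm = TRUE))
  hi <- pa_ann / pet_ann
  hi[!is.finite(hi) | pet_ann <= 0] <- NA_real_
  cls <- matrix(NA_character_, nrow(hi), ncol(hi))
  cls[!is.na(hi) & hi < 1] <- "arid"
  cls[!is.na(hi) & hi > 1] <- "humid"
  structure(
    list(
      hi = hi, pa_annual = pa_ann, pet_annual = pet_ann,
      aridity_class = cls, lat = pa$lat, lon = pa$lon
    ),
    class = "hydroclimate_field"
  )
}

#' Daily reference potential evapotranspiration (FAO-56 Penman-Monteith)
#'
#' The FAO-56 reference-crop formulation:
#' \deqn{PET = \frac{0.408\,\Delta\,(R_n - G) +
#'   \gamma\,\frac{900}{T+273}\,u_2\,(e_s - e_a)}
#'   {\Delta + \gamma\,(1 + 0.34\,u_2)}}
#' with the slope of the saturation vapour-pressure curve
#' \eqn{\Delta} (kPa per deg C), psychrometric constant
#' \eqn{\gamma = 0.000665 \times P} (kPa per deg C, P = 101.3 kPa at
#' sea level), available energy `Rn - G` in MJ m-2 d-1 and the vapour
#' pressure deficit `es - ea` in kPa. When net radiation is not
#' supplied it is taken as the sum of latent and sensible heat flux
#' (surface energy balance, ground flux neglected at the daily scale).
#' Results are clipped at zero.
#'
#' @param tair air temperature (deg C).
#' @param wind wind speed at 2 m (m s-1).
#' @param vpd vapour pressure deficit (hPa).
#' @param rn net radiation (W m-2); if `NULL`, `le + h` is used.
#' @param le,h latent / sensible heat flux (W m-2).
#' @param pressure surface air pressure (kPa, default 101.3).
#' @return daily PET (mm d-1), `NA` where any required input is
#'   missing.
#' @export
penman_monteith_pet <- function(tair, wind, vpd, rn = NULL, le = NULL,
                                h = NULL, pressure = 101.3) {
  if (is.null(rn)) {
    if (is.null(le) || is.null(h)) {
      stop("supply either `rn` or both `le` and `h`")
    }
    rn <- le + h
  }
  es <- 0.6108 * exp(17.27 * tair / (tair + 237.3))
  delta <- 4098 * es / (tair + 237.3)^2
  gamma <- 0.000665 * pressure
  rn_mj <- rn * 0.0864 # W m-2 -> MJ m-2 d-1
  vpd_kpa <- vpd / 10
  num <- 0.408 * delta * rn_mj + gamma * (900 / (tair + 273)) * wind * vpd_kpa
  den <- delta + gamma * (1 + 0.34 * wind)
  pmax(num / den, 0)
}

# active season for a single pixel (12 monthly climatology values)
.active_months_pixel <- function(t2m, pa, hi, lat,
                                 lower = 0.10, upper = 0.90) {
  active <- !is.na(t2m) & t2m > 0
  if (!is.na(hi) && hi < 1) {
    ord <- if (!is.na(lat) && lat < 0) c(7:12, 1:6) else 1:12
    total <- sum(pa[ord])
    ok <- rep(FALSE, 12L)
    if (!is.na(total) && total > 0) {
      frac <- cumsum(pa[ord]) / total
      ok[ord] <- frac > lower & frac <= upper
    }
    active <- active & ok
  }
  active
}

#' Meteorological active-season mask
#'
#' Months with climatological `T2m > 0` deg C; in water-limited cells
#' (`HI < 1`) further restricted to months where the running cumulative
#' precipitation fraction at month end lies in `(0.10, 0.90]` of the
#' annual total. For Southern-Hemisphere arid cells the accumulation
#' year runs July through June. An all-cold pixel yields an empty (but
#' valid) mask.
#'
#' @param t2m_clim monthly temperature climatology: a 12-vector for one
#'   pixel, or a `12 x lat x lon` array.
#' @param pa_clim monthly precipitation climatology, same shape.
#' @param hi humidity index (scalar or `lat x lon` matrix).
#' @param lat pixel latitude (scalar or vector of grid latitudes).
#' @return logical 12-vector, or a `lat x lon x 12` logical array.
#' @export
active_season_mask <- function(t2m_clim, pa_clim, hi, lat) {
  if (is.null(dim(t2m_clim)) || length(dim(t2m_clim)) == 1L) {
    stopifnot(length(t2m_clim) == 12L, length(pa_clim) == 12L)
    return(.active_months_pixel(t2m_clim, pa_clim, hi, lat))
  }
  d <- dim(t2m_clim)
  stopifnot(d[1] == 12L, identical(dim(pa_clim), d))
  out <- array(NA, c(d[2], d[3], 12L))
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      out[i, j, ] <- .active_months_pixel(
        t2m_clim[, i, j], pa_clim[, i, j], hi[i, j], lat[i]
      )
    }
  }
  out
}

#' Monthly climatology of a monthly field
#'
#' @param field a monthly [gridded_field()].
#' @return a `12 x lat x lon` array of multi-year monthly means.
#' @export
monthly_climatology <- function(field) {
  stopifnot(field$resolution == "monthly")
  d <- dim(field$values)
  out <- array(NA_real_, c(12L, d[2], d[3]))
  for (m in 1:12) {
    idx <- which(field$period == m)
    if (!length(idx)) next
    out[m, , ] <- apply(field$values[idx, , , drop = FALSE], c(2, 3),
      mean,
      na.rm = TRUE
    )
  }
  out
}
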