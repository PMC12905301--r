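#' Periods per year for a temporal resolution
#'
#' The pipeline uses fixed-length calendar years: daily data drop
#' Feb 29 so every year has 365 calendar days, and 8-daily data use 46
#' fixed periods restarting each Jan 1 (the final period is short).
#'
#' @param resolution one of `"daily"`, `"8-daily"`, `"monthly"`,
#'   `"annual"`.
#' @return integer number of within-year periods (365, 46, 12 or 1).
#' @export
periods_per_year <- function(resolution) {
  switch(match.arg(resolution, c("daily", "8-daily", "monthly", "annual")),
    "daily" = 365L, "8-daily" = 46L, "monthly" = 12L, "annual" = 1L
  )
}

#' Construct a gridded field
#'
#' The universal currency of the pipeline: one variable on a regular
#' lat/lon grid with a calendar-aware time axis. Values are stored as a
#' `time x lat x lon` array with `NA` marking missing data.
#'
#' @param values numeric array with dimensions
#'   `c(length(time$year), length(lat), length(lon))`. A matrix is
#'   accepted for single-pixel grids.
#' @param lat,lon numeric vectors of cell-center coordinates in degrees
#'   north / east, strictly monotone.
#' @param year integer vector of calendar years, one per time step.
#' @param period integer vector of within-year period indices
#'   (1-based, `<= periods_per_year(resolution)`).
#' @param resolution temporal resolution, see [periods_per_year()].
#' @param name,units variable name and physical units (required; readers
#'   and writers treat a missing units attribute as a schema error).
#' @return an object of class `gridded_field`.
#' @export
gridded_field <- function(values, lat, lon, year, period, resolution,
                          name = "x", units = "1") {
  resolution <- match.arg(resolution, c("daily", "8-daily", "monthly", "annual"))
  ppy <- periods_per_year(resolution)
  year <- as.integer(year)
  period <- as.integer(period)
  if (length(year) != length(period)) {
    stop("`year` and `period` must have the same length")
  }
  if (any(period < 1L) || any(period > ppy)) {
    stop("within-year period index must lie in 1..", ppy)
  }
  tcode <- year * ppy + period
  if (length(tcode) > 1L && any(diff(tcode) <= 0)) {
    stop("time axis must be strictly increasing")
  }
  values <- as.array(values)
  if (length(dim(values)) == 2L) {
    dim(values) <- c(dim(values), 1L)
  }
  if (length(dim(values)) != 3L) {
    stop("`values` must be a time x lat x lon array")
  }
  expected <- c(length(year), length(lat), length(lon))
  if (!identical(dim(values), as.integer(expected))) {
    stop(sprintf(
      "dim(values) is [%s] but time/lat/lon imply [%s]",
      paste(dim(values), collapse = ","), paste(expected, collapse = ",")
    ))
  }
  if (length(lat) > 1L && !all(diff(lat) > 0) && !all(diff(lat) < 0)) {
    stop("`lat` must be strictly monotone")
  }
  if (length(lon) > 1L && !all(diff(lon) > 0) && !all(diff(lon) < 0)) {
    stop("`lon` must be strictly monotone")
  }
  structure(
    list(
      name = name, units = units,
      lat = as.numeric(lat), lon = as.numeric(lon),
      year = year, period = period,
      resolution = resolution,
      values = values
    ),
    class = "gridded_field"
  )
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf(
    "<gridded_field> %s [%s]  %d x %d grid, %d steps (%s, %d-%d), %.1f%% missing\n",
    x$name, x$units, length(x$lat), length(x$lon), length(x$year),
    x$resolution, min(x$year), max(x$year),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.gridded_field <- function(x) dim(x$values)

n_years_field <- function(field) length(unique(field$year))

#' Extract the time series at one pixel
#'
#' @param field a [gridded_field()].
#' @param i,j latitude and longitude indices.
#' @return numeric vector of length `length(field$year)`.
#' @export
field_series <- function(field, i, j) {
  as.numeric(field$values[, i, j])
}

stopifnot_same_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$lat, b$lat)) || !isTRUE(all.equal(a$lon, b$lon))) {
    stop("fields are on different grids; regrid first")
  }
}

stopifnot_aligned <- function(a, b) {
  stopifnot_same_grid(a, b)
  if (!identical(a$year, b$year) || !identical(a$period, b$period) ||
    !identical(a$resolution, b$resolution)) {
    stop("fields have misaligned time axes")
  }
}

#' Apply a function to every pixel series, returning a lat x lon matrix
#'
#' @param field a [gridded_field()].
#' @param fn function taking a numeric series, returning a scalar.
#' @return matrix `length(lat) x length(lon)`.
#' @export
map_pixels <- function(field, fn) {
  apply(field$values, c(2, 3), fn)
}

# Build a field like `template` but with new values (and optionally a
# new time axis / metadata).
field_like <- function(template, values, year = template$year,
                       period = template$period,
                       resolution = template$resolution,
                       name = template$name, units = template$units) {
  gridded_field(values, template$lat, template$lon, year, period,
    resolution,
    name = name, units = units
  )
}
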