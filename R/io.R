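# Self-describing gridded text I/O.
#
# A gridded field is stored as one JSON document carrying the same
# schema a CF-convention gridded file would: variable name, mandatory
# units attribute, lat/lon cell centers, the calendar time axis
# (year + within-year period + resolution) and the value array with
# missing values as nulls. Full-precision serialization makes the
# write -> read round trip bit-exact.

.grid_schema <- "cloudsens-grid-1"

#' Write a gridded field to a self-describing JSON file
#'
#' @param field a [gridded_field()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  doc <- list(
    schema = .grid_schema,
    name = field$name, units = field$units,
    resolution = field$resolution,
    lat = field$lat, lon = field$lon,
    year = field$year, period = field$period,
    dim = dim(field$values),
    values = as.vector(field$values)
  )
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(doc, path,
    digits = I(17), auto_unbox = TRUE, na = "null", null = "null"
  )
  invisible(path)
}

#' Read a gridded field written by [write_gridded()]
#'
#' Validates the schema: missing required keys (including the units
#' attribute) or a non-monotonic time axis are rejected with an
#' explicit error.
#'
#' @param path file path.
#' @return a [gridded_field()].
#' @export
read_gridded <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  needed <- c(
    "schema", "name", "units", "resolution", "lat", "lon",
    "year", "period", "dim", "values"
  )
  absent <- setdiff(needed, names(doc))
  if (length(absent)) {
    stop(sprintf(
      "gridded file %s lacks required attribute(s): %s",
      path, paste(absent, collapse = ", ")
    ))
  }
  if (!identical(doc$schema, .grid_schema)) {
    stop("unrecognized gridded schema: ", doc$schema)
  }
  vals <- as.numeric(doc$values)
  dim(vals) <- doc$dim
  gridded_field(vals, doc$lat, doc$lon, doc$year, doc$period,
    doc$resolution,
    name = doc$name, units = doc$units
  )
}

#' Write site records to CSV
#'
#' One CSV holding all records in long form, with `site_id`, `lat`,
#' `lon` repeated per row; column dictionary: `gpp` g C m-2 d-1, `pa`
#' mm d-1, `swin` W m-2, `tair` degC, `wind` m s-1, `le`/`h` W m-2,
#' `vpd` hPa.
#'
#' @param records list of [site_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_site_records <- function(records, path) {
  tabs <- lapply(records, function(r) {
    cbind(
      data.frame(site_id = r$site_id, lat = r$lat, lon = r$lon),
      r$data
    )
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read site records written by [write_site_records()]
#'
#' @param path CSV path.
#' @return list of [site_record()]s.
#' @export
read_site_records <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$date <- as.Date(tab$date)
  lapply(split(tab, tab$site_id), function(d) {
    site_record(
      site_id = d$site_id[1], lat = d$lat[1], lon = d$lon[1],
      data = d[setdiff(names(d), c("site_id", "lat", "lon"))]
    )
  })
}
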