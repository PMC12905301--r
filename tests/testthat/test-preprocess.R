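# calendar-period detrending and Z-scoring -----------------------------

test_that("detrending removes exact linear and constant interannual signals", {
  # one calendar period, three years: exactly linear values
  f <- series_field(c(10, 12, 14), resolution = "annual")
  expect_error(detrend_calendar(f), "annual")

  f <- gridded_field(array(c(10, 12, 14), c(3, 1, 1)), 45, 10,
    year = 2001:2003, period = rep(1L, 3), "monthly"
  )
  d <- detrend_calendar(f)
  expect_equal(as.numeric(d$values), c(0, 0, 0))
  expect_equal(d$trend_fit$a[1, 1, 1], 2)

  fc <- gridded_field(array(c(5, 5, 5), c(3, 1, 1)), 45, 10,
    year = 2001:2003, period = rep(1L, 3), "monthly"
  )
  dc <- detrend_calendar(fc)
  expect_equal(dc$trend_fit$a[1, 1, 1], 0)
  expect_equal(as.numeric(dc$values), c(0, 0, 0))
})

test_that("short records bypass detrending per the long-record rule", {
  set.seed(1)
  vals <- rnorm(8 * 12)
  f <- gridded_field(array(vals, c(96, 1, 1)), 45, 10,
    year = rep(2001:2008, each = 12), period = rep(1:12, 8), "monthly"
  )
  d <- detrend_calendar(f, min_years_detrend = 10)
  expect_identical(as.numeric(d$values), vals)
  expect_false(d$detrended_flag[1, 1])
  d2 <- detrend_calendar(f, min_years_detrend = 5)
  expect_true(d2$detrended_flag[1, 1])
  expect_false(identical(as.numeric(d2$values), vals))
})

test_that("Z-scoring fulfils the per-period mean-0 sd-1 contract", {
  # residuals (-1, 0, 1) standardize to themselves (sd exactly 1)
  f <- gridded_field(array(c(-1, 0, 1), c(3, 1, 1)), 45, 10,
    year = 2001:2003, period = rep(1L, 3), "monthly"
  )
  z <- zscore_calendar(f, min_valid_years = 3, skip_detrend = TRUE)
  expect_equal(as.numeric(z$values), c(-1, 0, 1))

  # identical value every year: sigma = 0 -> all missing
  fc <- gridded_field(array(rep(7, 4), c(4, 1, 1)), 45, 10,
    year = 2001:2004, period = rep(1L, 4), "monthly"
  )
  zc <- zscore_calendar(fc, skip_detrend = TRUE)
  expect_true(all(is.na(zc$values)))

  # seeded multi-year field: per-period cross-year mean/sd contract
  set.seed(42)
  ny <- 20L
  f3 <- gridded_field(array(rnorm(ny * 12 * 2 * 2), c(ny * 12, 2, 2)),
    c(0, 10), c(0, 10),
    year = rep(2001:(2000 + ny), each = 12),
    period = rep(1:12, ny), "monthly"
  )
  z3 <- standardize_field(f3)
  for (p in 1:12) {
    sl <- z3$values[z3$period == p, , , drop = FALSE]
    mns <- apply(sl, c(2, 3), mean)
    sds <- apply(sl, c(2, 3), sd)
    expect_lt(max(abs(mns)), 1e-10)
    expect_lt(max(abs(sds - 1)), 1e-10)
  }
  expect_true(zscore_calendar(f3, skip_detrend = TRUE)$detrended_flag[1, 1] == FALSE)
})

test_that("standardizing an already standardized field is idempotent", {
  set.seed(9)
  f <- gridded_field(array(rnorm(10 * 12), c(120, 1, 1)), 45, 10,
    year = rep(2001:2010, each = 12), period = rep(1:12, 10), "monthly"
  )
  z1 <- standardize_field(f)
  z2 <- zscore_calendar(z1, skip_detrend = TRUE)
  expect_lt(max(abs(z2$values - z1$values)), 1e-10)
})

# temporal compositing ---------------------------------------------------

test_that("temporal compositing averages member steps per calendar rules", {
  # constant daily series -> constant 8-daily series
  f <- gridded_field(array(3, c(365, 1, 1)), 45, 10,
    year = rep(2001L, 365), period = 1:365, "daily"
  )
  e <- temporal_composite(f, "8-daily")
  expect_equal(dim(e$values)[1], 46L)
  expect_true(all(e$values == 3))

  # the 46th period averages exactly the remaining 5 days (361..365)
  f2 <- gridded_field(array(as.numeric(1:365), c(365, 1, 1)), 45, 10,
    year = rep(2001L, 365), period = 1:365, "daily"
  )
  e2 <- temporal_composite(f2, "8-daily")
  expect_equal(e2$values[46, 1, 1], mean(361:365))
  expect_equal(e2$values[1, 1, 1], mean(1:8))

  # monthly 1..12 -> annual mean 6.5
  fm <- gridded_field(array(as.numeric(1:12), c(12, 1, 1)), 45, 10,
    year = rep(2001L, 12), period = 1:12, "monthly"
  )
  expect_equal(temporal_composite(fm, "annual")$values[1, 1, 1], 6.5)

  expect_error(temporal_composite(fm, "monthly"), "coarser")

  # 50% member-validity rule
  v <- rep(2, 12)
  v[1:7] <- NA
  fv <- gridded_field(array(v, c(12, 1, 1)), 45, 10,
    year = rep(2001L, 12), period = 1:12, "monthly"
  )
  expect_true(is.na(temporal_composite(fv, "annual")$values[1, 1, 1]))
  v[1:5] <- 2 # now only 2 of 12 missing
  fv2 <- gridded_field(array(v, c(12, 1, 1)), 45, 10,
    year = rep(2001L, 12), period = 1:12, "monthly"
  )
  expect_false(is.na(temporal_composite(fv2, "annual")$values[1, 1, 1]))
})

# regridding -------------------------------------------------------------

test_that("box-mean regridding averages member cells and conserves means", {
  # four 0.5-degree cells symmetric about the equator -> exact mean 2.5
  f <- gridded_field(array(c(1, 3, 2, 4), c(1, 2, 2)), c(-0.25, 0.25),
    c(0.25, 0.75),
    year = 2001L, period = 1L, "annual"
  )
  tgt <- grid_spec(0, 0.5)
  r <- regrid_box_mean(f, tgt)
  expect_equal(r$values[1, 1, 1], 2.5)

  # constant field stays constant on any target grid
  set.seed(3)
  lat <- seq(-59.5, 59.5, by = 1)
  lon <- seq(-179.5, 179.5, by = 1)
  fc <- gridded_field(array(7, c(1, length(lat), length(lon))), lat, lon,
    year = 2001L, period = 1L, "annual"
  )
  tgt2 <- grid_spec(seq(-59, 59, by = 2), seq(-179, 179, by = 2))
  expect_lt(max(abs(regrid_box_mean(fc, tgt2)$values - 7)), 1e-12)
  expect_true(all(abs(regrid_bilinear(fc, tgt2)$values - 7) < 1e-12))

  # conservation of the area-weighted mean of a fully valid field
  vals <- array(rnorm(length(lat) * length(lon)), c(1, length(lat), length(lon)))
  fr <- gridded_field(vals, lat, lon, 2001L, 1L, "annual")
  rr <- regrid_box_mean(fr, tgt2)
  w_src <- matrix(cos(lat * pi / 180), length(lat), length(lon))
  src_mean <- sum(w_src * vals[1, , ]) / sum(w_src)
  # target weights: sum of member-cell cosines (2 source rows per target row)
  w_tgt_lat <- cos((tgt2$lat - 0.5) * pi / 180) + cos((tgt2$lat + 0.5) * pi / 180)
  w_tgt <- matrix(w_tgt_lat, length(tgt2$lat), length(tgt2$lon))
  tgt_mean <- sum(w_tgt * rr$values[1, , ]) / sum(w_tgt)
  expect_lt(abs(tgt_mean - src_mean), 1e-10)

  expect_error(regrid_box_mean(f, grid_spec(80, 80)), "no source cell")
})

test_that("bilinear interpolation is the identity at source cell centers", {
  set.seed(4)
  lat <- seq(10, 20, by = 2.5)
  lon <- seq(100, 110, by = 2.5)
  f <- gridded_field(array(rnorm(2 * 5 * 5), c(2, 5, 5)), lat, lon,
    year = 2001:2002, period = c(1L, 1L), "annual"
  )
  r <- regrid_bilinear(f, grid_spec(lat, lon))
  expect_equal(r$values, f$values, tolerance = 1e-12)
})

# site filters and matching ----------------------------------------------

test_that("site filters apply the span and mean-GPP thresholds", {
  mk <- function(days, gpp) {
    site_record("S", 45, 10, data.frame(
      date = as.Date("2001-01-01") + seq_len(days) - 1,
      gpp = gpp, pa = 1, swin = 200, tair = 15, wind = 2, le = 80,
      h = 40, vpd = 8
    ))
  }
  short <- mk(round(2.9 * 365.25) - 1, 5) # 2.9-year span
  low <- mk(round(5 * 365.25), 0.05) # productive span, barren flux
  good <- mk(round(5 * 365.25), 2)
  kept <- filter_sites(list(short, low, good))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$data$gpp[1], 2)
})

test_that("vegetation mask applies the strict GPP threshold", {
  v <- array(0, c(4, 2, 2))
  v[, 1, 1] <- 0 # barren
  v[, 1, 2] <- 0.1 # exactly at the floor: excluded ("over")
  v[, 2, 1] <- 1 # vegetated
  v[, 2, 2] <- 0.100001
  f <- gridded_field(v, c(0, 10), c(0, 10), 2001:2004, rep(1L, 4), "annual")
  m <- vegetation_mask(f, 0.1)
  expect_identical(m, matrix(c(FALSE, TRUE, FALSE, TRUE), 2, 2))
})

test_that("nearest-grid matching minimizes great-circle distance", {
  lat <- seq(40.125, 59.875, by = 0.25)
  lon <- seq(0.125, 19.875, by = 0.25)
  nt <- 2L
  f <- gridded_field(
    array(seq_len(nt * length(lat) * length(lon)), c(nt, length(lat), length(lon))),
    lat, lon, 2001:2002, c(1L, 1L), "annual"
  )
  # site exactly at a cell center
  m0 <- match_nearest_grid(list(lat = 50.125, lon = 10.125), f)
  expect_equal(c(m0$lat, m0$lon), c(50.125, 10.125))
  # off-center site: brute-force oracle over all cells
  site <- list(lat = 50.10, lon = 10.10)
  g <- expand.grid(i = seq_along(lat), j = seq_along(lon))
  d <- geosphere::distHaversine(
    cbind(site$lon, site$lat), cbind(lon[g$j], lat[g$i])
  )
  best <- g[which.min(d), ]
  m1 <- match_nearest_grid(site, f)
  expect_equal(m1$lat_index, best$i)
  expect_equal(m1$lon_index, best$j)
  expect_equal(c(m1$lat, m1$lon), c(50.125, 10.125))
  # equidistant pair straddling the equator: tie-break to lower |lat|...
  f2 <- gridded_field(array(1:2, c(1, 2, 1)), c(-1, 1), 0, 2001L, 1L, "annual")
  m2 <- match_nearest_grid(list(lat = 0, lon = 0), f2)
  expect_equal(m2$lat_index, 1L) # equal |lat|: first in (|lat|, lon) order
  expect_error(match_nearest_grid(list(lat = 70, lon = 0), f), "outside")
})

# cloud-property derivations ---------------------------------------------

test_that("grid-mean COT is the cloud-fraction-weighted optical thickness", {
  cf <- series_field(c(0, 0.5, 1, 0.25), "annual")
  cot <- series_field(c(10, 10, 12, 8), "annual")
  g <- grid_mean_cot(cf, cot)
  expect_equal(as.numeric(g$values), c(0, 5, 12, 2))
  expect_true(all(g$values <= cot$values))
  bad <- series_field(c(0, 1.5, 1, 0.2), "annual")
  expect_error(grid_mean_cot(bad, cot), "0, 1")
})

test_that("VOD night/day ratio guards the division", {
  night <- series_field(c(0.4, 0.5, 0.3), "annual")
  day <- series_field(c(0.5, 0.5, 0), "annual")
  r <- vod_night_day_ratio(night, day)
  expect_equal(as.numeric(r$values), c(0.8, 1, NA))
})

test_that("ISCCP reclassification places point masses and conserves totals", {
  h <- matrix(0, 8, 7)
  # COT = 2 (bin 1.3-3.6), CTP = 300 hPa (bin 180-310) -> cirrus
  h[3, 2] <- 0.4
  cls <- reclassify_isccp(h)
  expect_equal(unname(cls[["cirrus"]]), 0.4)
  expect_equal(sum(cls), 0.4)
  # COT = 30 (bin 23-60), CTP = 800 hPa -> low thick cloud: stratus
  h2 <- matrix(0, 8, 7)
  h2[6, 7] <- 0.2 # COT 23-60, CTP 800-1100
  cls2 <- reclassify_isccp(h2)
  expect_equal(unname(cls2[["stratus"]]), 0.2)
  # random histogram: totals conserved to 1e-12
  set.seed(8)
  h3 <- matrix(runif(56), 8, 7)
  expect_lt(abs(sum(reclassify_isccp(h3)) - sum(h3)), 1e-12)
  # bin edges straddling a class boundary are rejected
  expect_error(
    reclassify_isccp(h3, cot_edges = c(0, 2, 5, 9.4, 23, 60, 100, 140, 150)),
    "straddles"
  )
})
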