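# Umbrella pipeline: simulate -> standardize -> hydro -> sens -> attr
# -> project, with a manifest for reproducibility.

#' Pipeline configuration
#'
#' Bundles the synthetic-world configuration with every analysis
#' threshold. All thresholds must be positive and the moving window
#' odd.
#'
#' @param world a [world_config()].
#' @param veg_gpp_floor vegetation-mask threshold on multi-year mean
#'   GPP (g C m-2 d-1).
#' @param vif_threshold collinearity gate on the maximum VIF.
#' @param alpha significance level used for sensitivity maps and lag
#'   profiles.
#' @param min_n_subannual,min_n_monthly,min_n_annual minimum sample
#'   sizes per temporal scale.
#' @param baseline_years projection baseline window (years).
#' @param window attribution moving-window size (odd cells).
#' @param l_max maximum lag (periods) for the lag-response profile.
#' @param min_years_detrend_sites site records shorter than this are
#'   not detrended (years).
#' @param out_dir output directory or `NULL` for in-memory only.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(world = world_config(),
                            veg_gpp_floor = 0.1,
                            vif_threshold = 5,
                            alpha = 0.001,
                            min_n_subannual = 30L,
                            min_n_monthly = 12L,
                            min_n_annual = 30L,
                            baseline_years = 5L,
                            window = 3L,
                            l_max = 8L,
                            min_years_detrend_sites = 10L,
                            out_dir = NULL) {
  thr <- c(
    veg_gpp_floor, vif_threshold, alpha, min_n_subannual,
    min_n_monthly, min_n_annual, baseline_years, window, l_max,
    min_years_detrend_sites
  )
  if (any(thr <= 0)) stop("all thresholds must be positive")
  if (window %% 2L != 1L) stop("window must be odd")
  structure(
    list(
      world = world, veg_gpp_floor = veg_gpp_floor,
      vif_threshold = vif_threshold, alpha = alpha,
      min_n_subannual = as.integer(min_n_subannual),
      min_n_monthly = as.integer(min_n_monthly),
      min_n_annual = as.integer(min_n_annual),
      baseline_years = as.integer(baseline_years),
      window = as.integer(window), l_max = as.integer(l_max),
      min_years_detrend_sites = as.integer(min_years_detrend_sites),
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the [pipeline_config()] and [world_config()]
#' arguments; a `world:` block holds the generator settings (function
#' mappings keep their defaults).
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  wargs <- y$world %||% list()
  world <- do.call(world_config, wargs)
  pargs <- y[setdiff(names(y), "world")]
  do.call(pipeline_config, c(list(world = world), pargs))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline on the synthetic world
#'
#' Executes simulate, standardize, hydro, sens (8-daily and monthly
#' sensitivity maps, HI-shaping fit, lag-response summary), attr
#' (annual attribution) and project (CF change/trend driven GPP with
#' regional series). With an output directory, writes the gridded
#' fields, map layers, regional CSV and a JSON manifest (config,
#' seed, versions, file list); reruns with the same seed are
#' numerically identical.
#'
#' @param config a [pipeline_config()].
#' @return a list with components `world`, `standardized`, `hydro`,
#'   `sensitivity`, `attribution`, `projection` and `manifest`
#'   (invisibly returns the same when writing to disk).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  world <- .stage("simulate", make_world(config$world))

  std <- .stage("standardize", {
    gpp8 <- standardize_field(world$fields$gpp)
    cf8 <- standardize_field(world$fields$cf)
    pa8 <- standardize_field(world$fields$pa)
    par8 <- standardize_field(world$fields$par)
    to_monthly <- function(f) {
      if (f$resolution == "monthly") f else temporal_composite(f, "monthly")
    }
    gpp_m <- standardize_field(to_monthly(world$fields$gpp))
    cf_m <- standardize_field(to_monthly(world$fields$cf))
    list(
      gpp = gpp8, cf = cf8, pa = pa8, par = par8,
      gpp_monthly = gpp_m, cf_monthly = cf_m
    )
  })

  hydro <- .stage("hydro", {
    # monthly amounts: per-period means scale with the member count
    monthly_total <- function(f) {
      if (f$resolution == "monthly") {
        return(f)
      }
      m <- temporal_composite(f, "monthly")
      members <- tabulate(period_mapping(f$resolution, "monthly"), 12L)
      m$values <- sweep(m$values, 1, members[m$period], "*")
      m
    }
    pa_m <- monthly_total(world$fields$pa)
    pet_m <- monthly_total(world$fields$pet)
    hy <- humidity_index(pa_m, pet_m)
    t2m_m <- if (world$fields$t2m$resolution == "monthly") {
      world$fields$t2m
    } else {
      temporal_composite(world$fields$t2m, "monthly")
    }
    active <- active_season_mask(
      monthly_climatology(t2m_m),
      monthly_climatology(pa_m), hy$hi, world$lat
    )
    c(hy, list(active_months = active))
  })

  veg <- vegetation_mask(world$fields$gpp, config$veg_gpp_floor)

  sens <- .stage("sens", {
    map8 <- sensitivity_map(std$gpp, std$cf,
      mask = veg,
      min_n = config$min_n_subannual, alpha = config$alpha
    )
    mapm <- sensitivity_map(std$gpp_monthly, std$cf_monthly,
      mask = veg,
      min_n = config$min_n_monthly, alpha = config$alpha
    )
    ok <- !is.na(mapm$S) & !is.na(hydro$hi) & hydro$hi > 0
    hi_fit <- univariate_sensitivity(mapm$S[ok], log(hydro$hi[ok]),
      min_n = 10L
    )
    # lag-response profile per vegetated pixel (8-daily GPP* on PA*)
    nlat <- length(world$lat)
    nlon <- length(world$lon)
    eff <- matrix(NA_integer_, nlat, nlon)
    for (i in seq_len(nlat)) {
      for (j in seq_len(nlon)) {
        if (!isTRUE(veg[i, j])) next
        prof <- lag_response_profile(
          field_series(std$gpp, i, j), field_series(std$pa, i, j),
          l = config$l_max, alpha = config$alpha,
          min_n = config$min_n_subannual
        )
        eff[i, j] <- prof$effective_response_period
      }
    }
    list(
      map_8daily = map8, map_monthly = mapm,
      hi_shaping = hi_fit, effective_response = eff
    )
  })

  attrib <- .stage("attr", {
    ann <- lapply(
      world$fields[c("gpp", "cf", "t2m", "q")],
      temporal_composite, "annual"
    )
    deltas <- lapply(ann, year_to_year_deltas)
    list(
      map = annual_attribution(deltas$gpp, deltas$cf, deltas$t2m,
        deltas$q,
        window = config$window, mask = veg,
        min_n = config$min_n_annual,
        vif_threshold = config$vif_threshold
      ),
      annual = ann
    )
  })

  proj <- .stage("project", {
    cf_ann <- attrib$annual$cf
    dcf <- cf_change_series(cf_ann, config$baseline_years)
    dgpp <- gpp_change_from_cf(attrib$map$beta_cf, dcf)
    cf_tr <- trend_map(cf_ann)
    ggpp <- gpp_trend_from_cf(attrib$map$beta_cf, cf_tr$gamma)
    regions <- regional_series(dgpp, hydro$hi, veg)
    list(
      dcf = dcf, delta_gpp_cf = dgpp, cf_trend = cf_tr,
      gpp_trend_cf = ggpp, regional = regions
    )
  })

  result <- list(
    world = world, standardized = std, hydro = hydro,
    sensitivity = sens, attribution = attrib, projection = proj,
    veg_mask = veg
  )

  if (!is.null(config$out_dir)) {
    result$manifest <- .stage(
      "write",
      write_pipeline_outputs(result, config)
    )
    return(invisible(result))
  }
  result
}

# writes declared outputs + manifest, returns the manifest
write_pipeline_outputs <- function(result, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (v in names(result$world$fields)) {
    p <- file.path(out, paste0(v, ".json"))
    write_gridded(result$world$fields[[v]], p)
    files <- c(files, p)
  }
  mat_field <- function(m, name, units = "1") {
    gridded_field(array(m, c(1L, dim(m))), result$world$lat,
      result$world$lon,
      year = max(result$world$year), period = 1L,
      resolution = "annual", name = name, units = units
    )
  }
  layers <- list(
    sensitivity_monthly = result$sensitivity$map_monthly$S,
    beta_cf_annual = result$attribution$map$beta_cf,
    hi = result$hydro$hi,
    gpp_trend_cf = result$projection$gpp_trend_cf
  )
  for (nm in names(layers)) {
    p <- file.path(out, paste0(nm, ".json"))
    write_gridded(mat_field(layers[[nm]], nm), p)
    files <- c(files, p)
  }
  p <- file.path(out, "regional_series.csv")
  utils::write.csv(result$projection$regional, p, row.names = FALSE)
  files <- c(files, p)

  cfg <- config
  cfg$world <- cfg$world[!vapply(cfg$world, is.function, logical(1))]
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(cfg, cfg_path,
    digits = NA, auto_unbox = TRUE,
    na = "null", force = TRUE
  )
  manifest <- list(
    package = "cloudsens",
    version = as.character(utils::packageVersion("cloudsens")),
    r_version = R.version.string,
    seed = config$world$seed,
    config_file = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = basename(files),
    created = format(Sys.time(), tz = "UTC")
  )
  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE)
  manifest
}
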