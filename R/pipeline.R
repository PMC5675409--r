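# Pipeline orchestration: a single configuration object, file-based stages
# (each stage reads only the previous stages' documented outputs), and a
# run-all driver. Every model constant is surfaced here with its standard
# value as the default.

#' Default pipeline configuration
#'
#' Nested list with one block per stage. All model constants (carbon
#' fraction 0.475, eps_max 0.542/0.429 gC MJ-1, FPAR bounds 0.001/0.95,
#' PAR fraction 0.5, IDW power 2, Angstrom a/b 0.25/0.50, bucket capacity
#' 100 mm) are here and can be overridden from YAML.
#'
#' @param seed Integer seed for the synthetic world.
#' @return Nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    world = list(n_years = 13L, grid_rows = 20L, grid_cols = 20L,
                 pixel_size = 500, n_stations = 9L,
                 precip_annual_mean = 295, precip_gradient = 0.5,
                 temp_annual_mean = 3.36,
                 npp_precip_coupling = 0.8, npp_temp_coupling = 0,
                 temp_precip_correlation = -0.3,
                 noise_sd = 0.05, latitude = 44),
    interpolation = list(power = 2),
    solar = list(angstrom_a = 0.25, angstrom_b = 0.50),
    casa = list(fpar_min = 0.001, fpar_max = 0.95, par_fraction = 0.5,
                bucket_capacity_mm = 100,
                ndvi_percentiles = c(0.05, 0.95),
                eps_max_grassland = 0.542, eps_max_shrub = 0.429),
    validation = list(n_plots = 46L, obs_noise_sd = 0, through_month = 7L,
                      carbon_fraction = 0.475),
    livestock = list(trend = -2000),
    attribution = list(fdr = FALSE, hist_bin_width = 0.1)),
    class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; the schema is
#' validated before any stage runs.
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_config(if (!is.null(user$seed)) user$seed else 1L))
  for (block in names(user)) {
    if (!block %in% names(cfg))
      stop(sprintf("config error: unknown block '%s'", block))
    if (is.list(user[[block]])) {
      bad <- setdiff(names(user[[block]]), names(cfg[[block]]))
      if (length(bad))
        stop(sprintf("config error: unknown key '%s.%s'", block, bad[1]))
      cfg[[block]][names(user[[block]])] <- user[[block]]
    } else cfg[[block]] <- user[[block]]
  }
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' Write a pipeline configuration to YAML
#'
#' @param config `pipeline_config`.
#' @param path Output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  w <- cfg$world
  if (w$n_years < 2) stop("config error: world.n_years must be >= 2")
  if (w$grid_rows < 1 || w$grid_cols < 1)
    stop("config error: world grid shape must be positive")
  if (cfg$interpolation$power <= 0)
    stop("config error: interpolation.power must be > 0")
  if (cfg$casa$fpar_min < 0 || cfg$casa$fpar_max > 1 ||
      cfg$casa$fpar_min >= cfg$casa$fpar_max)
    stop("config error: need 0 <= fpar_min < fpar_max <= 1")
  if (cfg$validation$through_month < 1 || cfg$validation$through_month > 12)
    stop("config error: validation.through_month must be in 1..12")
  cfg
}

config_world <- function(cfg) {
  w <- cfg$world
  world_config(seed = cfg$seed, n_years = w$n_years,
               grid_shape = c(w$grid_rows, w$grid_cols),
               pixel_size = w$pixel_size, n_stations = w$n_stations,
               precip_annual_mean = w$precip_annual_mean,
               precip_gradient = w$precip_gradient,
               temp_annual_mean = w$temp_annual_mean,
               temp_precip_correlation = w$temp_precip_correlation,
               npp_precip_coupling = w$npp_precip_coupling,
               npp_temp_coupling = w$npp_temp_coupling,
               noise_sd = w$noise_sd, latitude = w$latitude)
}

# each stage writes into <out>/<stage>.tmp, renamed on success, so a
# failed stage never leaves partial outputs in place
with_stage_dir <- function(out_dir, stage, f) {
  final <- file.path(out_dir, stage)
  tmp <- paste0(final, ".tmp")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  res <- f(tmp)
  unlink(final, recursive = TRUE)
  file.rename(tmp, final)
  ok <- TRUE
  invisible(res)
}

stack_paths <- function(dir, prefix) {
  paths <- Sys.glob(file.path(dir, sprintf("%s_*_[0-9][0-9].asc", prefix)))
  if (!length(paths))
    stop(sprintf("missing input: no '%s_<year>_<mm>.asc' rasters in %s %s",
                 prefix, dir,
                 if (dir.exists(dir)) "" else "(directory does not exist)"),
         call. = FALSE)
  sort(paths)
}

require_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing input: %s", path), call. = FALSE)
  path
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

log_stage <- function(stage, grid = NULL, t0 = NULL) {
  msg <- sprintf("[grasscasa] stage=%s%s%s", stage,
                 if (!is.null(grid)) paste0(" grid=", format(grid)) else "",
                 if (!is.null(t0)) sprintf(" elapsed=%.2fs",
                                           as.numeric(Sys.time()) - t0) else "")
  message(msg)
}

#' Run pipeline stages
#'
#' Executes the requested stages in order against a shared output
#' directory. Stages:
#' \describe{
#'   \item{simulate}{generate the synthetic world and write its inputs
#'     (reflectance and land-cover rasters, station/plot/livestock CSVs,
#'     the configuration as YAML) under `inputs/`}
#'   \item{ndvi}{reflectance -> maximum-value-composited monthly NDVI}
#'   \item{interpolate}{station records -> temperature / precipitation /
#'     solar-radiation rasters}
#'   \item{npp}{the CASA model -> monthly NPP rasters}
#'   \item{aggregate}{annual and seasonal NPP rasters, regional mean
#'     series with anomalies, trend and autocorrelation}
#'   \item{validate}{plot-level observed vs estimated NPP and the
#'     regression/RMSE/bias suite}
#'   \item{attribute}{pixel-wise correlation and partial-correlation maps
#'     (annual + spring/summer/autumn, precipitation and temperature),
#'     their histogram summaries, and the county correlation table}
#' }
#' Re-running a stage with unchanged inputs reproduces its outputs
#' byte-identically. Missing upstream outputs fail fast naming the file.
#'
#' @param config A `pipeline_config`, or the path of a YAML config.
#' @param out_dir Output directory.
#' @param stages Character vector of stages, in pipeline order.
#' @return Invisibly, a list of headline results (validation statistics,
#'   regional series, map summaries) for the stages that produce them.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate", "ndvi", "interpolate",
                                    "npp", "aggregate", "validate",
                                    "attribute")) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    res <- switch(stage,
      simulate = stage_simulate(config, out_dir),
      ndvi = stage_ndvi(config, out_dir),
      interpolate = stage_interpolate(config, out_dir),
      npp = stage_npp(config, out_dir),
      aggregate = stage_aggregate(config, out_dir),
      validate = stage_validate(config, out_dir),
      attribute = stage_attribute(config, out_dir),
      stop(sprintf("unknown stage '%s'", stage)))
    results[[stage]] <- res
    log_stage(stage, t0 = t0)
  }
  invisible(results)
}

stage_simulate <- function(cfg, out_dir) {
  world <- make_world(config_world(cfg))
  plots <- make_validation_plots(world, cfg$validation$n_plots,
                                 cfg$validation$obs_noise_sd,
                                 through_month = cfg$validation$through_month)
  stock <- make_livestock_series(world, cfg$livestock$trend)
  with_stage_dir(out_dir, "inputs", function(d) {
    write_raster_stack(world$red, d, "red")
    write_raster_stack(world$nir, d, "nir")
    write_ascii_grid(world$landcover + 0, world$grid,
                     file.path(d, "landcover.asc"))
    write_ascii_grid(world$counties + 0, world$grid,
                     file.path(d, "counties.asc"))
    write_stations(world$stations, file.path(d, "stations.csv"))
    utils::write.csv(plots[setdiff(names(plots), "true_npp")],
                     file.path(d, "plots.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(stock, file.path(d, "livestock.csv"),
                     row.names = FALSE, quote = FALSE)
    write_config(cfg, file.path(d, "config.yaml"))
  })
  invisible(world)
}

stage_ndvi <- function(cfg, out_dir) {
  inp <- file.path(out_dir, "inputs")
  red <- read_raster_stack(stack_paths(inp, "red"), "red", "reflectance")
  nir <- read_raster_stack(stack_paths(inp, "nir"), "nir", "reflectance")
  if (!grids_identical(red$grid, nir$grid))
    stop_grid_mismatch(red$grid, nir$grid, "'red' and 'nir'")
  nd <- red
  nd$values <- array(compute_ndvi(red$values, nir$values), dim(red$values))
  nd$variable <- "ndvi"; nd$units <- ""
  nd <- composite_monthly(nd)
  with_stage_dir(out_dir, "ndvi", function(d) write_raster_stack(nd, d))
  invisible(nd)
}

stage_interpolate <- function(cfg, out_dir) {
  stations <- read_stations(require_file(file.path(out_dir, "inputs",
                                                   "stations.csv")))
  lcv <- read_ascii_grid(require_file(file.path(out_dir, "inputs",
                                                "landcover.asc")))
  climate <- build_climate_fields(stations, lcv$grid,
                                  power = cfg$interpolation$power,
                                  latitude = cfg$world$latitude,
                                  angstrom_a = cfg$solar$angstrom_a,
                                  angstrom_b = cfg$solar$angstrom_b)
  with_stage_dir(out_dir, "climate", function(d) {
    write_raster_stack(climate$temperature, d, "temperature")
    write_raster_stack(climate$precipitation, d, "precipitation")
    write_raster_stack(climate$solar, d, "solar")
  })
  invisible(climate)
}

read_climate_dir <- function(out_dir) {
  d <- file.path(out_dir, "climate")
  list(temperature = read_raster_stack(stack_paths(d, "temperature"),
                                       "temperature", "degC"),
       precipitation = read_raster_stack(stack_paths(d, "precipitation"),
                                         "precipitation", "mm"),
       solar = read_raster_stack(stack_paths(d, "solar"),
                                 "solar", "MJ m-2 month-1"))
}

stage_npp <- function(cfg, out_dir) {
  ndvi <- read_raster_stack(stack_paths(file.path(out_dir, "ndvi"), "ndvi"),
                            "ndvi", "")
  climate <- read_climate_dir(out_dir)
  lcv <- read_ascii_grid(require_file(file.path(out_dir, "inputs",
                                                "landcover.asc")))
  cp <- default_class_params()
  cp$eps_max[cp$name == "grassland"] <- cfg$casa$eps_max_grassland
  cp$eps_max[cp$name == "shrub"] <- cfg$casa$eps_max_shrub
  cp <- calibrate_class_bounds(ndvi, lcv$values, cp,
                               probs = cfg$casa$ndvi_percentiles)
  fit <- run_casa(ndvi, climate, lcv$values, cp,
                  fpar_min = cfg$casa$fpar_min, fpar_max = cfg$casa$fpar_max,
                  par_fraction = cfg$casa$par_fraction,
                  bucket_capacity_mm = cfg$casa$bucket_capacity_mm,
                  latitude = cfg$world$latitude)
  with_stage_dir(out_dir, "npp", function(d) {
    write_raster_stack(fit$npp, d, "npp")
    utils::write.csv(fit$class_params, file.path(d, "class_params.csv"),
                     row.names = FALSE, quote = FALSE)
  })
  invisible(fit)
}

stage_aggregate <- function(cfg, out_dir) {
  npp <- read_raster_stack(stack_paths(file.path(out_dir, "npp"), "npp"),
                           "npp", "gC m-2 month-1")
  climate <- read_climate_dir(out_dir)
  ann <- annual_npp(npp)
  seas <- lapply(c("spring", "summer", "autumn"),
                 function(s) seasonal_npp(npp, s))
  names(seas) <- c("spring", "summer", "autumn")
  series <- regional_mean_series(ann)
  precip_y <- regional_mean_series(climate_yearly(climate$precipitation,
                                                  fun = "sum"))
  temp_y <- regional_mean_series(climate_yearly(climate$temperature,
                                                fun = "mean"))
  tab <- data.frame(year = series$year, npp = series$value,
                    precip = precip_y$value, temp = temp_y$value,
                    anomaly_npp = series$anomaly,
                    anomaly_precip = precip_y$anomaly,
                    anomaly_temp = temp_y$anomaly)
  trend <- linear_trend(tab$year, tab$npp)
  acf_tab <- series_acf(tab$npp)
  with_stage_dir(out_dir, "aggregate", function(d) {
    write_raster_stack(ann, d, "npp_annual")
    for (s in names(seas)) write_raster_stack(seas[[s]], d,
                                              paste0("npp_", s))
    utils::write.csv(tab, file.path(d, "regional_series.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(acf_tab, file.path(d, "npp_acf.csv"),
                     row.names = FALSE, quote = FALSE)
    write_json_file(trend, file.path(d, "npp_trend.json"))
  })
  invisible(list(annual = ann, seasonal = seas, series = tab, trend = trend))
}

stage_validate <- function(cfg, out_dir) {
  npp <- read_raster_stack(stack_paths(file.path(out_dir, "npp"), "npp"),
                           "npp", "gC m-2 month-1")
  plots <- utils::read.csv(require_file(file.path(out_dir, "inputs",
                                                  "plots.csv")))
  tab <- extract_estimates(npp, plots, cfg$validation$through_month,
                           cfg$validation$carbon_fraction)
  stats <- validation_stats(tab$observed_npp, tab$estimated_npp)
  with_stage_dir(out_dir, "validate", function(d) {
    utils::write.csv(tab, file.path(d, "validation.csv"),
                     row.names = FALSE, quote = FALSE)
    write_json_file(stats, file.path(d, "validation_stats.json"))
  })
  invisible(list(table = tab, stats = stats))
}

stage_attribute <- function(cfg, out_dir) {
  npp <- read_raster_stack(stack_paths(file.path(out_dir, "npp"), "npp"),
                           "npp", "gC m-2 month-1")
  climate <- read_climate_dir(out_dir)
  lcv <- read_ascii_grid(require_file(file.path(out_dir, "inputs",
                                                "landcover.asc")))
  counties <- read_ascii_grid(require_file(file.path(out_dir, "inputs",
                                                     "counties.asc")))
  mask <- lcv$values > 0
  periods <- c(list(annual = 1:12), season_definition()[c("spring", "summer",
                                                          "autumn")])
  maps <- list(); summaries <- list()
  for (pn in names(periods)) {
    months <- periods[[pn]]
    npp_y <- climate_yearly(npp, months, "sum")
    pr_y <- climate_yearly(climate$precipitation, months, "sum")
    tm_y <- climate_yearly(climate$temperature, months, "mean")
    combos <- list(
      precip = list(target = pr_y, control = NULL),
      precip_partial = list(target = pr_y, control = tm_y),
      temp = list(target = tm_y, control = NULL),
      temp_partial = list(target = tm_y, control = pr_y))
    for (cn in names(combos)) {
      key <- paste(pn, cn, sep = "_")
      maps[[key]] <- correlation_map(npp_y, combos[[cn]]$target,
                                     combos[[cn]]$control, mask = mask,
                                     fdr = cfg$attribution$fdr)
      summaries[[key]] <- map_summary(maps[[key]],
                                      cfg$attribution$hist_bin_width)
    }
  }
  ctab <- county_table(npp, climate$precipitation, climate$temperature,
                       counties$values, mask = mask)
  with_stage_dir(out_dir, "attribute", function(d) {
    for (key in names(maps)) {
      write_ascii_grid(maps[[key]]$r, maps[[key]]$grid,
                       file.path(d, sprintf("r_%s.asc", key)))
      write_ascii_grid(maps[[key]]$p, maps[[key]]$grid,
                       file.path(d, sprintf("p_%s.asc", key)))
    }
    write_json_file(summaries, file.path(d, "map_summaries.json"))
    utils::write.csv(ctab, file.path(d, "county_table.csv"),
                     row.names = FALSE, quote = FALSE)
  })
  invisible(list(maps = maps, summaries = summaries, county_table = ctab))
}
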