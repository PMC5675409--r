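# Synthetic study region: a semi-arid steppe with a west->east moisture
# gradient, precipitation concentrated in July-September, a sparse national
# station network and clip-plot biomass surveys. Latent productivity is
# built with *known* couplings to the generated climate so that model
# recovery and attribution sign tests have analytic expectations.

# Monthly climatologies (fractions / degC offsets). Winter months carry no
# production; July-September hold ~59% of annual precipitation.
PRECIP_MONTH_SHARE <- c(0.02, 0.02, 0.03, 0.05, 0.07, 0.10,
                        0.24, 0.21, 0.14, 0.06, 0.04, 0.02)
NPP_MONTH_SHARE <- c(0, 0, 0.02, 0.06, 0.12, 0.18, 0.22, 0.20, 0.12, 0.06,
                     0.02, 0)
TEMP_MONTH_OFFSET <- c(-21, -17, -8, 2, 10, 16, 19, 17, 10, 2, -9, -18) - 0.25
SUNSHINE_FRACTION <- c(0.68, 0.70, 0.70, 0.68, 0.66, 0.62, 0.55, 0.58,
                       0.64, 0.68, 0.68, 0.66)

#' Configuration of a synthetic study region
#'
#' Defaults emulate the study conditions: a 13-year record, 9 stations,
#' ~295 mm mean annual precipitation, a 3.36 degC mean annual temperature,
#' precipitation increasing (and with it productivity) from west to east.
#'
#' @param seed Integer RNG seed; the whole world is a deterministic function
#'   of the configuration including the seed.
#' @param n_years Number of simulated years (>= 2).
#' @param grid_shape Integer `(rows, cols)` of the pixel grid.
#' @param pixel_size Pixel edge (m); 500 m matches the reflectance product.
#' @param n_stations Number of meteorological stations (>= 2).
#' @param precip_annual_mean Regional mean annual precipitation (mm).
#' @param precip_gradient Fractional west->east change in annual
#'   precipitation across the grid (e.g. 0.5 = +50% east edge vs west edge,
#'   applied as a linear ramp centred on the regional mean).
#' @param temp_annual_mean Regional mean annual temperature (degC).
#' @param temp_lat_gradient North->south temperature increase across the
#'   grid (degC).
#' @param precip_year_sd SD of the lognormal interannual precipitation
#'   factor (dimensionless).
#' @param temp_year_sd SD of the interannual temperature anomaly (degC).
#' @param temp_precip_correlation Correlation between yearly temperature
#'   anomalies and yearly (log) precipitation factors; negative means wet
#'   years run cool, as is typical of monsoon-edge steppe.
#' @param npp_precip_coupling Gain (>= 0) of latent productivity on the
#'   fractional annual precipitation anomaly.
#' @param npp_temp_coupling Signed gain of latent productivity per degC of
#'   annual temperature anomaly (0 = temperature acts only through any
#'   correlation with precipitation).
#' @param npp_per_mm Base productivity per mm of mean annual precipitation
#'   (gC m-2 mm-1); 0.8 puts the regional mean near 240 gC m-2 yr-1.
#' @param noise_sd SD of multiplicative pixel-year noise on latent
#'   productivity (fraction).
#' @param spatial_noise_sd SD of the static multiplicative pixel noise on
#'   base precipitation (fraction), centred within columns so the
#'   configured gradient is exact in column means.
#' @param latitude Representative site latitude (degrees N), used for
#'   sunshine-hour climatology and solar geometry.
#' @param shrub_fraction,barren_fraction Fractions of pixels assigned to
#'   the shrub and non-vegetated land-cover classes.
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_years = 13L,
                         grid_shape = c(20L, 20L),
                         pixel_size = 500,
                         n_stations = 9L,
                         precip_annual_mean = 295,
                         precip_gradient = 0.5,
                         temp_annual_mean = 3.36,
                         temp_lat_gradient = 1.5,
                         precip_year_sd = 0.20,
                         temp_year_sd = 0.9,
                         temp_precip_correlation = -0.3,
                         npp_precip_coupling = 0.8,
                         npp_temp_coupling = 0,
                         npp_per_mm = 0.8,
                         noise_sd = 0.05,
                         spatial_noise_sd = 0.10,
                         latitude = 44,
                         shrub_fraction = 0.15,
                         barren_fraction = 0.05) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  cfg$n_years <- as.integer(n_years)
  cfg$grid_shape <- as.integer(grid_shape)
  cfg$n_stations <- as.integer(n_stations)
  if (is.na(cfg$seed)) stop("world_config: 'seed' must be an integer")
  if (cfg$n_years < 2L) stop("world_config: 'n_years' must be >= 2")
  if (length(cfg$grid_shape) != 2L || any(is.na(cfg$grid_shape)) ||
      any(cfg$grid_shape < 1L))
    stop("world_config: 'grid_shape' must be two positive integers")
  if (cfg$n_stations < 2L) stop("world_config: 'n_stations' must be >= 2")
  if (!is.finite(precip_annual_mean) || precip_annual_mean <= 0)
    stop("world_config: 'precip_annual_mean' must be > 0")
  if (npp_precip_coupling < 0)
    stop("world_config: 'npp_precip_coupling' must be >= 0")
  if (noise_sd < 0 || spatial_noise_sd < 0)
    stop("world_config: noise SDs must be >= 0")
  class(cfg) <- "world_config"
  cfg
}

with_world_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic world
#'
#' Builds, deterministically for a given configuration, the full set of
#' coupled inputs the pipeline consumes: per-month red/NIR reflectance
#' rasters (back-solved from a target NDVI with red fixed at 0.08), a
#' land-cover class raster, monthly station records (temperature,
#' precipitation, sunshine), a 3 x 3 county partition, plus the latent
#' ground truth (pixel-level monthly productivity and the exact climate
#' stacks and couplings it was generated from).
#'
#' Construction, per pixel p and year y:
#' \itemize{
#'   \item annual precipitation `P[p,y] = base(p) * f[y]` with `base` a
#'     west->east linear ramp times static (column-centred) noise and `f`
#'     a region-wide lognormal yearly factor;
#'   \item latent annual productivity
#'     `A[p,y] = npp_per_mm * base(p) * (1 + gP * dP[y]) * (1 + gT * dT[y])
#'      * (1 + noise)`, where `dP` is the fractional precipitation anomaly
#'     and `dT` the temperature anomaly (degC);
#'   \item monthly latent productivity spreads `A` over a fixed
#'     growing-season template (December-February identically zero); NDVI
#'     is proportional to monthly latent productivity and reflectance is
#'     back-solved so NDVI = (NIR - red)/(NIR + red) holds exactly.
#' }
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world`: list with `config`, `grid`,
#'   `red`, `nir` (monthly_stack reflectance), `landcover` (matrix of class
#'   codes: 0 barren, 1 grassland, 2 shrub), `stations` (data frame),
#'   `counties` (integer matrix), and `truth` (latent monthly/annual
#'   productivity, pixel climate stacks, yearly anomalies, couplings).
#' @export
make_world <- function(config) {
  if (!inherits(config, "world_config"))
    stop("make_world: 'config' must come from world_config()")
  with_world_seed(config$seed, build_world(config))
}

build_world <- function(cfg) {
  rows <- cfg$grid_shape[1]; cols <- cfg$grid_shape[2]
  npix <- rows * cols
  grid <- raster_grid(rows, cols, origin_x = 0,
                      origin_y = rows * cfg$pixel_size,
                      pixel_size = cfg$pixel_size)
  years <- seq_len(cfg$n_years)
  n_t <- cfg$n_years * 12L
  yr_idx <- rep(years, each = 12L)
  mo_idx <- rep(1:12, cfg$n_years)

  # --- static spatial structure -------------------------------------------
  colfrac <- matrix((seq_len(cols) - 0.5) / cols, rows, cols, byrow = TRUE)
  rowfrac <- matrix((seq_len(rows) - 0.5) / rows, rows, cols)
  ramp <- 1 + cfg$precip_gradient * (colfrac - 0.5)

  # land cover: grassland matrix with scattered shrub / barren pixels
  u <- matrix(stats::runif(npix), rows, cols)
  landcover <- matrix(1L, rows, cols)
  landcover[u < cfg$shrub_fraction + cfg$barren_fraction] <- 2L
  landcover[u < cfg$barren_fraction] <- 0L
  veg <- landcover > 0L

  # static multiplicative noise, centred within each column over vegetated
  # pixels so the configured west->east gradient is exact in vegetated
  # column means (not merely in expectation)
  center_columns <- function(m) {
    for (j in seq_len(ncol(m))) {
      idx <- if (any(veg[, j])) veg[, j] else rep(TRUE, nrow(m))
      m[idx, j] <- m[idx, j] - mean(m[idx, j])
    }
    m
  }
  eps <- center_columns(matrix(stats::rnorm(npix, 0, cfg$spatial_noise_sd),
                               rows, cols))
  base_precip <- pmax(cfg$precip_annual_mean * ramp * (1 + eps), 1)

  # --- region-wide yearly anomalies ---------------------------------------
  zp <- stats::rnorm(cfg$n_years)
  zt <- stats::rnorm(cfg$n_years)
  f_year <- exp(cfg$precip_year_sd * zp)        # precipitation factor
  rho <- cfg$temp_precip_correlation
  t_anom <- cfg$temp_year_sd * (rho * zp + sqrt(max(0, 1 - rho^2)) * zt)
  dP <- f_year / mean(f_year) - 1               # fractional precip anomaly
  dT <- t_anom - mean(t_anom)

  # --- pixel climate stacks (the generating truth) ------------------------
  precip <- array(0, c(rows, cols, n_t))
  temp <- array(0, c(rows, cols, n_t))
  for (i in seq_len(n_t)) {
    y <- yr_idx[i]; m <- mo_idx[i]
    precip[, , i] <- base_precip * f_year[y] * PRECIP_MONTH_SHARE[m]
    temp[, , i] <- cfg$temp_annual_mean + TEMP_MONTH_OFFSET[m] +
      cfg$temp_lat_gradient * (rowfrac - 0.5) + t_anom[y]
  }

  # --- latent productivity -------------------------------------------------
  base_npp <- cfg$npp_per_mm * base_precip
  base_npp[landcover == 0L] <- 0
  annual <- array(0, c(rows, cols, cfg$n_years))
  for (y in years) {
    fac <- (1 + cfg$npp_precip_coupling * dP[y]) *
      (1 + cfg$npp_temp_coupling * dT[y])
    dev <- if (cfg$noise_sd > 0)
      center_columns(base_npp * matrix(stats::rnorm(npix, 0, cfg$noise_sd),
                                       rows, cols)) else 0
    annual[, , y] <- pmax(fac * (base_npp + dev), 0)
  }
  latent <- array(0, c(rows, cols, n_t))
  for (i in seq_len(n_t))
    latent[, , i] <- annual[, , yr_idx[i]] * NPP_MONTH_SHARE[mo_idx[i]]

  # --- NDVI target and reflectance back-solve -----------------------------
  peak <- max(latent)
  scale <- if (peak > 0) 0.85 / peak else 0
  ndvi <- latent * scale
  barren <- array(landcover == 0L, c(rows, cols, n_t))
  ndvi[barren] <- 0.05                          # bare-soil background
  red <- array(0.08, c(rows, cols, n_t))
  nir <- red * (1 + ndvi) / (1 - ndvi)

  red_stack <- monthly_stack(red, grid, yr_idx, mo_idx, "red", "reflectance")
  nir_stack <- monthly_stack(nir, grid, yr_idx, mo_idx, "nir", "reflectance")

  # --- stations: jittered quasi-uniform layout, snapped to pixel centres --
  stations <- place_stations(grid, cfg$n_stations)
  centers <- pixel_centers(grid)
  recs <- vector("list", cfg$n_stations)
  sun_noise <- matrix(stats::rnorm(cfg$n_years * 12L, 0, 0.02),
                      cfg$n_years, 12L)
  N_month <- vapply(1:12, function(m) daylength_hours_month(m, cfg$latitude),
                    numeric(1))
  for (s in seq_len(cfg$n_stations)) {
    xf <- (stations$x[s] - grid$origin_x) / (cols * grid$pixel_size)
    yf <- (grid$origin_y - stations$y[s]) / (rows * grid$pixel_size)
    st_base <- cfg$precip_annual_mean * (1 + cfg$precip_gradient * (xf - 0.5))
    recs[[s]] <- data.frame(
      station_id = sprintf("S%02d", s),
      x = stations$x[s], y = stations$y[s],
      year = yr_idx, month = mo_idx,
      temp_c = cfg$temp_annual_mean + TEMP_MONTH_OFFSET[mo_idx] +
        cfg$temp_lat_gradient * (yf - 0.5) + t_anom[yr_idx],
      precip_mm = st_base * f_year[yr_idx] * PRECIP_MONTH_SHARE[mo_idx],
      sunshine_h = pmin(pmax(SUNSHINE_FRACTION[mo_idx] +
                               sun_noise[cbind(yr_idx, mo_idx)], 0), 1) *
        N_month[mo_idx])
  }
  stations_df <- do.call(rbind, recs)

  truth <- list(
    npp_monthly = monthly_stack(latent, grid, yr_idx, mo_idx,
                                "npp", "gC m-2 month-1"),
    npp_annual = annual,
    precipitation = monthly_stack(precip, grid, yr_idx, mo_idx,
                                  "precipitation", "mm"),
    temperature = monthly_stack(temp, grid, yr_idx, mo_idx,
                                "temperature", "degC"),
    base_precip = base_precip, base_npp = base_npp,
    precip_anomaly = dP, temp_anomaly = dT,
    couplings = c(precip = cfg$npp_precip_coupling,
                  temp = cfg$npp_temp_coupling))

  structure(list(config = cfg, grid = grid, red = red_stack, nir = nir_stack,
                 landcover = landcover, stations = stations_df,
                 counties = county_partition(grid), truth = truth),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %s, %d years, %d stations, seed %d\n",
              format(x$grid), x$config$n_years, x$config$n_stations,
              x$config$seed))
  invisible(x)
}

# Quasi-uniform jittered station layout snapped to pixel centres (so the
# zero-distance IDW rule is exercised at every station pixel).
place_stations <- function(grid, n) {
  k <- ceiling(sqrt(n))
  cells <- expand.grid(i = seq_len(k), j = seq_len(k))[seq_len(n), ]
  row <- pmin(grid$rows, pmax(1, round((cells$i - stats::runif(n, 0.2, 0.8)) *
                                         grid$rows / k + 0.5)))
  col <- pmin(grid$cols, pmax(1, round((cells$j - stats::runif(n, 0.2, 0.8)) *
                                         grid$cols / k + 0.5)))
  # de-duplicate coincident stations by shifting along rows
  key <- paste(row, col)
  while (anyDuplicated(key)) {
    d <- which(duplicated(key))
    row[d] <- (row[d] %% grid$rows) + 1L
    key <- paste(row, col)
  }
  data.frame(station_id = sprintf("S%02d", seq_len(n)),
             x = grid$origin_x + (col - 0.5) * grid$pixel_size,
             y = grid$origin_y - (row - 0.5) * grid$pixel_size)
}

#' Partition the grid into rectangular counties
#'
#' The default 3 x 3 block partition yields nine counties, one per station
#' of the emulated network.
#'
#' @param grid A [raster_grid()].
#' @param nx,ny Number of county columns and rows.
#' @return Integer matrix (rows x cols) of county ids `1..nx*ny`, numbered
#'   row-block by row-block.
#' @export
county_partition <- function(grid, nx = 3L, ny = 3L) {
  ci <- ceiling(seq_len(grid$rows) / (grid$rows / ny))
  cj <- ceiling(seq_len(grid$cols) / (grid$cols / nx))
  matrix((ci[row(matrix(0, grid$rows, grid$cols))] - 1L) * nx +
           cj[col(matrix(0, grid$rows, grid$cols))],
         grid$rows, grid$cols)
}

#' Sample clip-plot biomass observations from a world
#'
#' Emulates paired 0.5 m clip plots: at each sampled location the observed
#' above- plus below-ground dry biomass equals the latent productivity
#' accumulated over January..`through_month` divided by the carbon fraction
#' 0.475, plus optional observation noise — so with `obs_noise_sd = 0`,
#' converting biomass back to carbon reproduces the latent NPP exactly.
#'
#' @param world A [make_world()] result.
#' @param n_plots Number of plots (>= 1); the emulated survey used 46.
#' @param obs_noise_sd SD of additive noise on total biomass (g m-2).
#' @param year Survey year index (default the 11th year, the 2011 analogue
#'   of a 2001-2013 record).
#' @param through_month Last month included in the accumulated NPP the
#'   plots measure (default July).
#' @return Data frame with `plot_id, x, y, year, month, agb, bgb`
#'   (dry biomass, g m-2) and the hidden `true_npp` column (gC m-2).
#' @export
make_validation_plots <- function(world, n_plots = 46L, obs_noise_sd = 0,
                                  year = NULL, through_month = 7L) {
  stopifnot(inherits(world, "synthetic_world"))
  n_plots <- as.integer(n_plots)
  if (is.na(n_plots) || n_plots < 1L)
    stop("make_validation_plots: 'n_plots' must be >= 1")
  if (is.null(year)) year <- min(11L, world$config$n_years)
  if (!year %in% seq_len(world$config$n_years))
    stop("make_validation_plots: 'year' outside the simulated span")
  with_world_seed(world$config$seed + 1000L, {
    veg <- which(world$landcover > 0L, arr.ind = TRUE)
    pick <- veg[sample(nrow(veg), n_plots, replace = n_plots > nrow(veg)), ,
                drop = FALSE]
    grid <- world$grid
    x <- grid$origin_x + (pick[, 2] - 0.5) * grid$pixel_size
    y <- grid$origin_y - (pick[, 1] - 0.5) * grid$pixel_size
    keep <- world$truth$npp_monthly$year == year &
      world$truth$npp_monthly$month <= through_month
    npp <- apply(world$truth$npp_monthly$values[, , keep, drop = FALSE],
                 c(1, 2), sum)
    true_npp <- npp[pick]
    total_biomass <- pmax(true_npp / 0.475 +
                            stats::rnorm(n_plots, 0, obs_noise_sd), 0)
    data.frame(plot_id = sprintf("P%03d", seq_len(n_plots)),
               x = x, y = y, year = year, month = through_month,
               agb = 0.7 * total_biomass, bgb = 0.3 * total_biomass,
               true_npp = true_npp)
  })
}

#' Generate yearly livestock counts per county
#'
#' One sheep count and one large-livestock (cattle + horses) count per
#' county-year, with a linear trend; counts never go negative.
#'
#' @param world A [make_world()] result.
#' @param trend Change in standard-sheep units per county per year
#'   (negative = destocking).
#' @param base_sheep,base_large Mean initial herd sizes per county.
#' @return Data frame `county, year, sheep, large_livestock, standard_sheep`.
#' @export
make_livestock_series <- function(world, trend = -2000,
                                  base_sheep = 8e5, base_large = 5e4) {
  stopifnot(inherits(world, "synthetic_world"))
  with_world_seed(world$config$seed + 2000L, {
    counties <- sort(unique(as.vector(world$counties)))
    years <- seq_len(world$config$n_years)
    out <- expand.grid(county = counties, year = years)
    out <- out[order(out$county, out$year), ]
    county_scale <- stats::runif(length(counties), 0.6, 1.4)
    sheep <- pmax(base_sheep * county_scale[out$county] +
                    trend * (out$year - 1), 0)
    large <- pmax(base_large * county_scale[out$county] +
                    trend / 5 * (out$year - 1), 0)
    out$sheep <- round(sheep)
    out$large_livestock <- round(large)
    out$standard_sheep <- livestock_to_standard_sheep(out$large_livestock,
                                                      out$sheep)
    rownames(out) <- NULL
    out
  })
}
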