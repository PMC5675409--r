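# Station meteorology -> monthly raster fields.
# Interpolation is inverse-distance weighting on pixel centres; total solar
# radiation is derived from sunshine duration with the Angstrom-Prescott
# relation and standard (FAO-56) solar geometry.

#' Inverse-distance-weighted interpolation to a grid
#'
#' Weights are `d^-power` from each pixel centre to each station. A pixel
#' whose centre coincides with a station takes that station's value exactly
#' (zero-distance rule), and every interpolated value lies within the range
#' of the station values (maximum principle for positive weights).
#'
#' @param x,y Station coordinates (map units).
#' @param values Station values (same length).
#' @param grid Target [raster_grid()].
#' @param power IDW exponent (> 0), default 2.
#' @return Numeric matrix `rows x cols`.
#' @export
idw_interpolate <- function(x, y, values, grid, power = 2) {
  n <- length(values)
  if (n == 0L || length(x) != n || length(y) != n)
    stop("idw_interpolate: need at least one station with matching x/y/values")
  if (any(!is.finite(values)))
    stop("idw_interpolate: non-finite station values")
  w <- idw_weights(x, y, grid, power)
  matrix(w %*% values, grid$rows, grid$cols)
}

# normalised IDW weight matrix (n_pixels x n_stations); rows for pixels
# whose centre coincides with a station put all weight on that station
idw_weights <- function(x, y, grid, power) {
  n <- length(x)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("idw_interpolate: non-finite station coordinates")
  if (anyDuplicated(cbind(x, y)))
    stop("idw_interpolate: coincident duplicate stations")
  if (power <= 0) stop("idw_interpolate: 'power' must be > 0")
  ctr <- pixel_centers(grid)
  px <- as.vector(ctr$x); py <- as.vector(ctr$y)
  d2 <- outer(px, x, function(a, b) (a - b)^2) +
    outer(py, y, function(a, b) (a - b)^2)
  w <- d2^(-power / 2)
  hit <- which(d2 == 0, arr.ind = TRUE)
  if (nrow(hit)) {
    w[hit[, 1], ] <- 0
    w[hit] <- 1
  }
  w / rowSums(w)
}

#' Interpolate monthly station records onto the grid
#'
#' Runs [idw_interpolate()] per year-month for one station variable.
#'
#' @param stations Station data frame (see [read_stations()]).
#' @param variable Column to interpolate (`"temp_c"`, `"precip_mm"`,
#'   `"sunshine_h"`).
#' @param grid Target [raster_grid()].
#' @param power IDW exponent.
#' @return A [monthly_stack()].
#' @export
interpolate_stations <- function(stations, variable, grid, power = 2) {
  if (!variable %in% names(stations))
    stop(sprintf("interpolate_stations: no column '%s'", variable))
  ym <- unique(stations[c("year", "month")])
  ym <- ym[order(ym$year, ym$month), ]
  arr <- array(NA_real_, c(grid$rows, grid$cols, nrow(ym)))
  # station layouts rarely change month to month: cache the normalised
  # weight matrix per distinct set of contributing stations
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(ym))) {
    rec <- stations[stations$year == ym$year[i] & stations$month == ym$month[i], ]
    ok <- is.finite(rec[[variable]])
    if (!any(ok))
      stop(sprintf("no station has '%s' for %d-%02d", variable,
                   ym$year[i], ym$month[i]))
    rec <- rec[ok, ]
    key <- paste(rec$x, rec$y, collapse = ";")
    if (is.null(cache[[key]]))
      cache[[key]] <- idw_weights(rec$x, rec$y, grid, power)
    arr[, , i] <- matrix(cache[[key]] %*% rec[[variable]],
                         grid$rows, grid$cols)
  }
  monthly_stack(arr, grid, ym$year, ym$month, variable, "")
}

# ---- solar geometry (FAO-56) ---------------------------------------------

DAYS_IN_MONTH <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

solar_geometry_day <- function(doy, latitude) {
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  a <- -tan(phi) * tan(delta)
  ws <- acos(pmin(pmax(a, -1), 1))              # sunset hour angle
  Ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  list(Ra = pmax(Ra, 0), N = 24 * ws / pi)      # MJ m-2 day-1, hours
}

month_doys <- function(month) {
  first <- cumsum(c(0L, DAYS_IN_MONTH))[month] + 1L
  seq(first, length.out = DAYS_IN_MONTH[month])
}

#' Monthly extraterrestrial radiation
#'
#' Sum of daily top-of-atmosphere radiation over the calendar month
#' (365-day year).
#'
#' @param month Month 1..12.
#' @param latitude Latitude in degrees (|lat| < 66.5).
#' @return MJ m-2 month-1.
#' @export
extraterrestrial_radiation_month <- function(month, latitude) {
  g <- solar_geometry_day(month_doys(month), latitude)
  sum(g$Ra)
}

#' Monthly sum of astronomical day length
#'
#' @inheritParams extraterrestrial_radiation_month
#' @return Hours of possible sunshine in the month.
#' @export
daylength_hours_month <- function(month, latitude) {
  g <- solar_geometry_day(month_doys(month), latitude)
  sum(g$N)
}

#' Total solar radiation from sunshine duration
#'
#' Angstrom-Prescott relation `SOL = (a + b * n/N) * Ra` with monthly day
#' length `N` and extraterrestrial radiation `Ra` from standard solar
#' geometry. `n/N > 1` (recorded sunshine exceeding the astronomical
#' maximum) is clipped to 1 with a warning.
#'
#' @param sunshine_hours Observed monthly sunshine duration `n` (h), >= 0;
#'   vectorised.
#' @param month Month 1..12 (scalar or same length).
#' @param latitude Degrees, |lat| < 66.5.
#' @param a,b Angstrom coefficients (FAO defaults 0.25, 0.50).
#' @return MJ m-2 month-1; always in `[a*Ra, (a+b)*Ra]`, and monotone
#'   non-decreasing in `sunshine_hours`.
#' @export
solar_from_sunshine <- function(sunshine_hours, month, latitude = 44,
                                a = 0.25, b = 0.50) {
  if (any(sunshine_hours < 0, na.rm = TRUE))
    stop("solar_from_sunshine: sunshine_hours must be >= 0")
  if (abs(latitude) >= 66.5)
    stop("solar_from_sunshine: |latitude| must be < 66.5 degrees")
  month <- rep_len(month, length(sunshine_hours))
  Ra <- vapply(month, extraterrestrial_radiation_month, numeric(1),
               latitude = latitude)
  N <- vapply(month, daylength_hours_month, numeric(1), latitude = latitude)
  frac <- sunshine_hours / N
  if (any(frac > 1 + 1e-9, na.rm = TRUE))
    warning("solar_from_sunshine: n/N > 1 clipped to 1")
  frac <- pmin(frac, 1)
  (a + b * frac) * Ra
}

#' Build monthly climate fields from station records
#'
#' Interpolates temperature, precipitation and sunshine to the grid, then
#' converts sunshine to total solar radiation.
#'
#' @param stations Station data frame.
#' @param grid Target [raster_grid()].
#' @param power IDW exponent.
#' @param latitude Site latitude (degrees).
#' @param angstrom_a,angstrom_b Angstrom-Prescott coefficients.
#' @return List of [monthly_stack()]s: `temperature` (degC),
#'   `precipitation` (mm), `solar` (MJ m-2 month-1).
#' @export
build_climate_fields <- function(stations, grid, power = 2, latitude = 44,
                                 angstrom_a = 0.25, angstrom_b = 0.50) {
  validate_stations(stations)
  temp <- interpolate_stations(stations, "temp_c", grid, power)
  temp$variable <- "temperature"; temp$units <- "degC"
  precip <- interpolate_stations(stations, "precip_mm", grid, power)
  precip$variable <- "precipitation"; precip$units <- "mm"
  sun <- interpolate_stations(stations, "sunshine_h", grid, power)
  sol <- sun
  for (i in seq_along(sol$year))
    sol$values[, , i] <- matrix(
      solar_from_sunshine(as.vector(sun$values[, , i]), sun$month[i],
                          latitude, angstrom_a, angstrom_b),
      grid$rows, grid$cols)
  sol$variable <- "solar"; sol$units <- "MJ m-2 month-1"
  list(temperature = temp, precipitation = precip, solar = sol)
}
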