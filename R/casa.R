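# Modified CASA light-use-efficiency model:
#   NPP(x,t) = APAR(x,t) * eps(x,t)
#   APAR     = SOL * FPAR * 0.5
#   FPAR     = mean of NDVI- and simple-ratio-based linear estimates,
#              bounded to [0.001, 0.95]
#   eps      = Teps1 * Teps2 * Weps * eps_max
# with per-class NDVI/SR calibration bounds and eps_max, temperature stress
# from the monthly mean and the pixel's optimum temperature, and moisture
# stress from the ratio of estimated to potential evapotranspiration
# (Thornthwaite PET + a single-layer soil-moisture bucket).

#' Default per-class CASA parameters
#'
#' Maximum light-use efficiency: 0.542 gC MJ-1 for grassland and
#' 0.429 gC MJ-1 for shrub; the non-vegetated class produces nothing.
#'
#' @return Data frame with columns `class_id, name, eps_max`.
#' @export
default_class_params <- function() {
  data.frame(class_id = c(0L, 1L, 2L),
             name = c("barren", "grassland", "shrub"),
             eps_max = c(0, 0.542, 0.429))
}

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - red) / (NIR + red)`; where the denominator is zero the
#' result is missing (nodata).
#'
#' @param red,nir Surface reflectances in `[0, 1]` (vectorised).
#' @return NDVI in `[-1, 1]`, `NA` where `nir + red == 0`.
#' @export
compute_ndvi <- function(red, nir) {
  if (any(red < 0 | red > 1, na.rm = TRUE) ||
      any(nir < 0 | nir > 1, na.rm = TRUE))
    stop("compute_ndvi: reflectances must lie in [0, 1]")
  den <- nir + red
  out <- (nir - red) / den
  out[den == 0] <- NA_real_
  out
}

#' Maximum-value composite of sub-monthly layers
#'
#' Per-pixel maximum over the layers falling in each (year, month) —
#' the standard composite for suppressing cloud and atmospheric noise in
#' 8-day reflectance-derived NDVI. A pixel is nodata only if it is nodata
#' in every contributing layer.
#'
#' @param stack A [monthly_stack()] whose layers may repeat (year, month).
#' @return A [monthly_stack()] with one layer per (year, month).
#' @export
composite_monthly <- function(stack) {
  ym <- unique(data.frame(year = stack$year, month = stack$month))
  ym <- ym[order(ym$year, ym$month), ]
  if (nrow(ym) == length(stack$year)) {        # already one layer per month
    o <- order(stack$year, stack$month)
    return(monthly_stack(stack$values[, , o, drop = FALSE], stack$grid,
                         stack$year[o], stack$month[o], stack$variable,
                         stack$units))
  }
  arr <- array(NA_real_, c(stack$grid$rows, stack$grid$cols, nrow(ym)))
  for (i in seq_len(nrow(ym))) {
    sel <- stack$year == ym$year[i] & stack$month == ym$month[i]
    sub <- stack$values[, , sel, drop = FALSE]
    arr[, , i] <- apply(sub, c(1, 2), function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  }
  monthly_stack(arr, stack$grid, ym$year, ym$month, stack$variable,
                stack$units)
}

#' Simple ratio from NDVI
#'
#' `SR = (1 + NDVI) / (1 - NDVI)`, strictly increasing on `[-1, 1)`;
#' `NDVI = 1` maps to nodata.
#'
#' @param ndvi NDVI values (vectorised).
#' @return Simple ratio, >= 0.
#' @export
compute_sr <- function(ndvi) {
  out <- (1 + ndvi) / (1 - ndvi)
  out[!is.na(ndvi) & ndvi == 1] <- NA_real_
  out
}

linmap_clamp <- function(x, x0, x1, y0, y1) {
  y <- (x - x0) / (x1 - x0) * (y1 - y0) + y0
  pmin(pmax(y, min(y0, y1)), max(y0, y1))
}

#' FPAR from NDVI (per-class linear rescaling)
#'
#' Linear map sending the class NDVI minimum to `fpar_min` and the class
#' NDVI maximum to `fpar_max`, clamped to that interval (remote-sensing
#' inputs outside the calibration bounds are clamped, not rejected).
#'
#' @param ndvi NDVI values.
#' @param ndvi_min,ndvi_max Class calibration bounds (`ndvi_min < ndvi_max`).
#' @param fpar_min,fpar_max Global FPAR bounds, defaults 0.001 and 0.95.
#' @return FPAR in `[fpar_min, fpar_max]`.
#' @export
fpar_from_ndvi <- function(ndvi, ndvi_min, ndvi_max,
                           fpar_min = 0.001, fpar_max = 0.95) {
  if (any(ndvi_min >= ndvi_max))
    stop("fpar_from_ndvi: need ndvi_min < ndvi_max")
  linmap_clamp(ndvi, ndvi_min, ndvi_max, fpar_min, fpar_max)
}

#' FPAR from the simple ratio
#'
#' Same linear rescaling as [fpar_from_ndvi()] with the class SR bounds.
#'
#' @param sr Simple-ratio values.
#' @param sr_min,sr_max Class SR bounds (`sr_min < sr_max`).
#' @inheritParams fpar_from_ndvi
#' @return FPAR in `[fpar_min, fpar_max]`.
#' @export
fpar_from_sr <- function(sr, sr_min, sr_max,
                         fpar_min = 0.001, fpar_max = 0.95) {
  if (any(sr_min >= sr_max)) stop("fpar_from_sr: need sr_min < sr_max")
  linmap_clamp(sr, sr_min, sr_max, fpar_min, fpar_max)
}

#' Combine the two FPAR estimates
#'
#' Arithmetic mean of the NDVI- and SR-based estimates.
#'
#' @param fpar_ndvi,fpar_sr FPAR estimates in `[0.001, 0.95]`.
#' @return FPAR in `[0.001, 0.95]`.
#' @export
compute_fpar <- function(fpar_ndvi, fpar_sr) (fpar_ndvi + fpar_sr) / 2

#' Calibrate per-class NDVI and SR bounds from the NDVI history
#'
#' For each vegetated land-cover class, the NDVI bounds are percentiles
#' (default 5th and 95th) of all valid NDVI samples of that class over the
#' record, and the SR bounds are the simple ratio evaluated at those NDVI
#' percentiles.
#'
#' @param ndvi A [monthly_stack()] of NDVI.
#' @param landcover Integer class matrix on the same grid.
#' @param class_params Data frame from [default_class_params()] (supplies
#'   `eps_max` per class).
#' @param probs Lower/upper percentiles, default `c(0.05, 0.95)`.
#' @param min_samples Minimum valid samples per class (default 20).
#' @return `class_params` with columns `ndvi_min, ndvi_max, sr_min, sr_max`
#'   added for vegetated classes.
#' @export
calibrate_class_bounds <- function(ndvi, landcover,
                                   class_params = default_class_params(),
                                   probs = c(0.05, 0.95), min_samples = 20L) {
  stopifnot(inherits(ndvi, "monthly_stack"))
  if (!all(dim(landcover) == c(ndvi$grid$rows, ndvi$grid$cols)))
    stop("calibrate_class_bounds: landcover does not match the NDVI grid")
  cp <- class_params
  cp$ndvi_min <- cp$ndvi_max <- cp$sr_min <- cp$sr_max <- NA_real_
  for (k in seq_len(nrow(cp))) {
    if (cp$eps_max[k] <= 0) next                # non-vegetated: no bounds
    mask <- landcover == cp$class_id[k]
    if (!any(mask)) next
    samples <- ndvi$values[array(mask, dim(ndvi$values))]
    samples <- samples[is.finite(samples)]
    if (length(samples) < min_samples)
      stop(sprintf("class %s ('%s'): only %d valid NDVI samples (< %d)",
                   cp$class_id[k], cp$name[k], length(samples), min_samples))
    q <- stats::quantile(samples, probs, names = FALSE, type = 7)
    if (q[1] >= q[2])
      stop(sprintf("class %s ('%s'): degenerate NDVI bounds (%g, %g)",
                   cp$class_id[k], cp$name[k], q[1], q[2]))
    cp$ndvi_min[k] <- q[1]; cp$ndvi_max[k] <- q[2]
    cp$sr_min[k] <- compute_sr(q[1]); cp$sr_max[k] <- compute_sr(q[2])
  }
  cp
}

#' First temperature stress scalar
#'
#' `Teps1 = 0.8 + 0.02 * t_opt - 0.0005 * t_opt^2`, reflecting the
#' depression of light-use efficiency for pixels whose optimum growth
#' temperature is very low or very high; forced to 0 in months whose mean
#' temperature is at or below -10 degC (no production under deep frost),
#' and never negative.
#'
#' @param t_opt Optimum temperature (degC): the mean temperature of the
#'   month with the year's maximum NDVI.
#' @param t Monthly mean temperature (degC); used only for the -10 degC
#'   cutoff. Defaults to `t_opt` (no cutoff applied).
#' @return Stress scalar >= 0.
#' @export
temp_stress_1 <- function(t_opt, t = t_opt) {
  out <- pmax(0.8 + 0.02 * t_opt - 0.0005 * t_opt^2, 0)
  out[!is.na(t) & t <= -10] <- 0
  out
}

#' Second temperature stress scalar
#'
#' Double-logistic reduction of light-use efficiency as the monthly mean
#' temperature departs from the pixel optimum:
#' `Teps2 = 1.1814 / (1 + exp(0.2*(t_opt - 10 - t)))
#'                 / (1 + exp(0.3*(-t_opt - 10 + t)))`,
#' additionally capped at its `t = t_opt` value once `t` exceeds
#' `t_opt + 10` (hot months cannot be less stressed than the optimum).
#'
#' @param t Monthly mean temperature (degC).
#' @param t_opt Optimum temperature (degC).
#' @return Stress scalar in `[0, 1.1814)`.
#' @export
temp_stress_2 <- function(t, t_opt) {
  f <- function(tt) 1.1814 / (1 + exp(0.2 * (t_opt - 10 - tt))) /
    (1 + exp(0.3 * (-t_opt - 10 + tt)))
  out <- f(t)
  hot <- !is.na(t) & !is.na(t_opt) & t > t_opt + 10
  at_opt <- f(t_opt)
  out[hot] <- pmin(out[hot], if (length(at_opt) > 1) at_opt[hot] else at_opt)
  out
}

#' Moisture stress scalar
#'
#' `Weps = 0.5 + 0.5 * EET / PET`, in `[0.5, 1]`: 0.5 under complete
#' drought, 1 when actual evapotranspiration meets the potential demand.
#' `PET = 0` (no demand) is treated as the driest limit, 0.5.
#'
#' @param eet Estimated (actual) evapotranspiration (mm month-1).
#' @param pet Potential evapotranspiration (mm month-1).
#' @return Stress scalar in `[0.5, 1]`.
#' @export
moisture_stress <- function(eet, pet) {
  ratio <- ifelse(is.na(pet) | pet <= 0, 0, pmin(pmax(eet / pet, 0), 1))
  0.5 + 0.5 * ratio
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' `PET = 16 * (10 T / I)^alpha` (mm per standard 30-day month of 12-h
#' days), corrected for actual day length and month length; `T <= 0` gives
#' zero demand. `I` is the annual heat index, the sum over months of
#' `(T/5)^1.514` for positive monthly means.
#'
#' @param temp_monthly Numeric matrix `n_pixels x 12` (or vector of 12) of
#'   monthly mean temperature (degC) for one year.
#' @param latitude Degrees, for the day-length correction.
#' @return Matrix of the same shape: PET in mm month-1.
#' @export
thornthwaite_pet <- function(temp_monthly, latitude = 44) {
  tm <- if (is.matrix(temp_monthly)) temp_monthly else
    matrix(temp_monthly, nrow = 1)
  if (ncol(tm) != 12L) stop("thornthwaite_pet: need 12 monthly temperatures")
  tp <- pmax(tm, 0)
  I <- rowSums((tp / 5)^1.514)
  alpha <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  Nbar <- vapply(1:12, function(m)
    daylength_hours_month(m, latitude) / DAYS_IN_MONTH[m], numeric(1))
  corr <- matrix(Nbar / 12, nrow(tm), 12, byrow = TRUE) *
    matrix(DAYS_IN_MONTH / 30, nrow(tm), 12, byrow = TRUE)
  pet <- 16 * (10 * tp / pmax(I, 1e-12))^alpha * corr
  pet[I <= 0 | tp <= 0] <- 0
  if (is.matrix(temp_monthly)) pet else as.vector(pet)
}

#' Actual evapotranspiration from a soil-moisture bucket
#'
#' Single-layer bucket: each month, actual evapotranspiration is the
#' smaller of the Thornthwaite demand and the available water
#' (precipitation plus stored soil moisture); the store is then updated
#' and capped at the bucket capacity.
#'
#' @param precip,pet Matrices `n_pixels x n_months` (time in order).
#' @param capacity_mm Bucket capacity (mm), default 100.
#' @param initial_fraction Initial fill fraction of the bucket.
#' @return Matrix of EET (mm month-1), same shape, with `0 <= EET <= PET`.
#' @export
bucket_eet <- function(precip, pet, capacity_mm = 100,
                       initial_fraction = 0.5) {
  stopifnot(all(dim(precip) == dim(pet)))
  w <- rep(capacity_mm * initial_fraction, nrow(precip))
  eet <- matrix(0, nrow(precip), ncol(precip))
  for (t in seq_len(ncol(precip))) {
    supply <- precip[, t] + w
    eet[, t] <- pmin(pet[, t], supply)
    w <- pmin(pmax(w + precip[, t] - eet[, t], 0), capacity_mm)
  }
  eet
}

#' Light-use efficiency
#'
#' `eps = Teps1 * Teps2 * Weps * eps_max`; with all stress scalars at 1
#' this is the class maximum (0.542 gC MJ-1 for grassland, 0.429 for
#' shrub).
#'
#' @param t_eps1,t_eps2,w_eps Stress scalars.
#' @param eps_max Class maximum light-use efficiency (gC MJ-1).
#' @return Efficiency in gC MJ-1.
#' @export
light_use_efficiency <- function(t_eps1, t_eps2, w_eps, eps_max) {
  t_eps1 * t_eps2 * w_eps * eps_max
}

#' Absorbed photosynthetically active radiation
#'
#' `APAR = SOL * FPAR * 0.5`; the factor 0.5 is the fraction of total
#' solar radiation in the photosynthetically usable band.
#'
#' @param sol Total solar radiation (MJ m-2 month-1).
#' @param fpar Fraction of PAR absorbed by the canopy.
#' @param par_fraction PAR fraction of total radiation, default 0.5.
#' @return APAR (MJ m-2 month-1), at most `par_fraction * sol`.
#' @export
compute_apar <- function(sol, fpar, par_fraction = 0.5)
  sol * fpar * par_fraction

#' Monthly NPP from APAR and light-use efficiency
#'
#' @param apar APAR (MJ m-2 month-1).
#' @param eps Light-use efficiency (gC MJ-1).
#' @return NPP (gC m-2 month-1), >= 0; `NA` propagates.
#' @export
compute_npp_month <- function(apar, eps) pmax(apar * eps, 0)

#' Run the full CASA model over a monthly record
#'
#' Drives the light-use-efficiency model with monthly NDVI, climate fields
#' and a land-cover map. Per pixel and year the optimum temperature is the
#' mean temperature of the month with that year's maximum NDVI; the
#' moisture scalar comes from Thornthwaite PET and a soil-moisture bucket
#' run through the whole record in time order. December-February layers
#' are identically zero (snow cover and dormancy preclude production).
#'
#' @param ndvi NDVI [monthly_stack()], complete months for each year.
#' @param climate List with `temperature`, `precipitation`, `solar` stacks
#'   (as from [build_climate_fields()]), on the NDVI grid.
#' @param landcover Integer class matrix.
#' @param class_params Calibrated bounds from [calibrate_class_bounds()];
#'   if the bound columns are absent they are calibrated here.
#' @param fpar_min,fpar_max FPAR bounds.
#' @param par_fraction PAR fraction of total solar radiation.
#' @param bucket_capacity_mm Soil bucket capacity (mm).
#' @param latitude Degrees, for PET day-length correction.
#' @return List: `npp` ([monthly_stack()], gC m-2 month-1), plus the
#'   intermediate `fpar`, `eps` stacks and the `class_params` used.
#' @export
run_casa <- function(ndvi, climate, landcover,
                     class_params = NULL,
                     fpar_min = 0.001, fpar_max = 0.95,
                     par_fraction = 0.5, bucket_capacity_mm = 100,
                     latitude = 44) {
  stopifnot(inherits(ndvi, "monthly_stack"))
  for (nm in c("temperature", "precipitation", "solar")) {
    if (!grids_identical(climate[[nm]]$grid, ndvi$grid))
      stop_grid_mismatch(ndvi$grid, climate[[nm]]$grid,
                         sprintf("'ndvi' and climate '%s'", nm))
  }
  check_complete_months(ndvi)
  rows <- ndvi$grid$rows; cols <- ndvi$grid$cols; npix <- rows * cols
  years <- sort(unique(ndvi$year))
  n_t <- length(ndvi$year)

  if (is.null(class_params) || is.null(class_params$ndvi_min))
    class_params <- calibrate_class_bounds(
      ndvi, landcover,
      if (is.null(class_params)) default_class_params() else class_params)

  # flatten to pixel x time, aligned to the ndvi layer order
  align <- function(stk) {
    idx <- vapply(seq_len(n_t), function(i)
      layer_index(stk, ndvi$year[i], ndvi$month[i]), integer(1))
    matrix(stk$values[, , idx], npix, n_t)
  }
  nd <- matrix(ndvi$values, npix, n_t)
  tc <- align(climate$temperature)
  pr <- align(climate$precipitation)
  so <- align(climate$solar)
  lc <- as.vector(landcover)

  # per-class FPAR
  fpar <- matrix(NA_real_, npix, n_t)
  for (k in seq_len(nrow(class_params))) {
    sel <- lc == class_params$class_id[k]
    if (!any(sel)) next
    if (class_params$eps_max[k] <= 0 || is.na(class_params$ndvi_min[k])) {
      fpar[sel, ] <- 0
      next
    }
    fn <- fpar_from_ndvi(nd[sel, , drop = FALSE],
                         class_params$ndvi_min[k], class_params$ndvi_max[k],
                         fpar_min, fpar_max)
    fs <- fpar_from_sr(compute_sr(nd[sel, , drop = FALSE]),
                       class_params$sr_min[k], class_params$sr_max[k],
                       fpar_min, fpar_max)
    fpar[sel, ] <- compute_fpar(fn, fs)
  }

  # optimum temperature per pixel-year: temp of the month of max NDVI
  t_opt <- matrix(NA_real_, npix, n_t)
  for (y in years) {
    sel <- which(ndvi$year == y)
    nd_y <- nd[, sel, drop = FALSE]
    best <- max.col(replace(nd_y, is.na(nd_y), -Inf), ties.method = "first")
    t_opt_y <- tc[cbind(seq_len(npix), sel[best])]
    t_opt[, sel] <- t_opt_y
  }

  # moisture stress: Thornthwaite PET per pixel-year, bucket EET over time
  pet <- matrix(0, npix, n_t)
  for (y in years) {
    sel <- which(ndvi$year == y)
    pet[, sel] <- thornthwaite_pet(tc[, sel, drop = FALSE], latitude)
  }
  eet <- bucket_eet(pr, pet, bucket_capacity_mm)
  w_eps <- moisture_stress(eet, pet)

  t1 <- temp_stress_1(t_opt, tc)
  t2 <- temp_stress_2(tc, t_opt)
  eps_max_px <- class_params$eps_max[match(lc, class_params$class_id)]
  eps <- light_use_efficiency(t1, t2, w_eps, eps_max_px)
  apar <- compute_apar(so, fpar, par_fraction)
  npp <- compute_npp_month(apar, eps)
  npp[, ndvi$month %in% c(12L, 1L, 2L)] <- 0    # winter-zero rule

  shape <- function(m, nm, un) monthly_stack(array(m, c(rows, cols, n_t)),
                                             ndvi$grid, ndvi$year,
                                             ndvi$month, nm, un)
  list(npp = shape(npp, "npp", "gC m-2 month-1"),
       fpar = shape(fpar, "fpar", ""),
       eps = shape(eps, "eps", "gC MJ-1"),
       class_params = class_params)
}
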