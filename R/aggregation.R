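# Temporal aggregation: annual (growing-season) and seasonal NPP sums,
# regional mean series with anomalies, OLS trends and autocorrelation.

#' Meteorological season definition
#'
#' Spring = Mar-May, summer = Jun-Aug, autumn = Sep-Nov, winter =
#' Dec-Feb; the twelve months partition exactly.
#'
#' @return Named list of integer month vectors.
#' @export
season_definition <- function() {
  list(spring = c(3L, 4L, 5L), summer = c(6L, 7L, 8L),
       autumn = c(9L, 10L, 11L), winter = c(12L, 1L, 2L))
}

#' Annual (growing-season) NPP per pixel
#'
#' Sum of the twelve monthly layers with December, January and February
#' forced to zero: under snow cover and dormancy no production occurs, so
#' the annual total equals growing-season NPP.
#'
#' @param npp Monthly NPP [monthly_stack()] with complete years.
#' @return [monthly_stack()] with one layer per year (month slot = 12),
#'   units gC m-2 yr-1.
#' @export
annual_npp <- function(npp) {
  check_complete_months(npp)
  years <- sort(unique(npp$year))
  arr <- array(NA_real_, c(npp$grid$rows, npp$grid$cols, length(years)))
  winter <- npp$month %in% c(12L, 1L, 2L)
  for (i in seq_along(years)) {
    sel <- npp$year == years[i] & !winter
    arr[, , i] <- apply(npp$values[, , sel, drop = FALSE], c(1, 2), sum)
  }
  monthly_stack(arr, npp$grid, years, 12L, "npp_annual", "gC m-2 yr-1")
}

#' Seasonal NPP per pixel
#'
#' Sum of the monthly layers in the requested season for each year. Winter
#' is excluded from analysis (its NPP is identically zero) but summing it
#' is permitted so the seasonal partition identity can be checked.
#'
#' @param npp Monthly NPP [monthly_stack()].
#' @param season Name in `names(season_definition())` or an integer month
#'   vector.
#' @param seasons Season table, default [season_definition()].
#' @return [monthly_stack()] with one layer per year, units gC m-2 season-1.
#' @export
seasonal_npp <- function(npp, season, seasons = season_definition()) {
  months <- if (is.character(season)) seasons[[season]] else as.integer(season)
  if (is.null(months) || !length(months))
    stop(sprintf("seasonal_npp: unknown or empty season '%s'",
                 paste(season, collapse = ",")))
  years <- sort(unique(npp$year))
  arr <- array(NA_real_, c(npp$grid$rows, npp$grid$cols, length(years)))
  for (i in seq_along(years)) {
    sel <- npp$year == years[i] & npp$month %in% months
    if (!any(sel))
      stop(sprintf("seasonal_npp: no layers for season in year %d", years[i]))
    arr[, , i] <- apply(npp$values[, , sel, drop = FALSE], c(1, 2), sum)
  }
  lab <- if (is.character(season)) season else "season"
  monthly_stack(arr, npp$grid, years, max(months), paste0("npp_", lab),
                "gC m-2 season-1")
}

#' Seasonal or annual mean of a climate stack
#'
#' Per-pixel mean (temperature) or sum (precipitation) of the monthly
#' layers in the given months, per year.
#'
#' @param stack Climate [monthly_stack()].
#' @param months Integer months to include (default all twelve).
#' @param fun `"mean"` or `"sum"`.
#' @return [monthly_stack()] with one layer per year.
#' @export
climate_yearly <- function(stack, months = 1:12, fun = c("mean", "sum")) {
  fun <- match.arg(fun)
  f <- if (fun == "mean") function(v) mean(v) else function(v) sum(v)
  years <- sort(unique(stack$year))
  arr <- array(NA_real_, c(stack$grid$rows, stack$grid$cols, length(years)))
  for (i in seq_along(years)) {
    sel <- stack$year == years[i] & stack$month %in% months
    if (!any(sel)) stop("climate_yearly: no layers selected")
    arr[, , i] <- apply(stack$values[, , sel, drop = FALSE], c(1, 2), f)
  }
  monthly_stack(arr, stack$grid, years, max(months), stack$variable,
                stack$units)
}

#' Regional mean series with anomalies
#'
#' Mean over valid (non-nodata, optionally masked) pixels for each yearly
#' layer, plus the anomaly from the period mean. Anomalies sum to zero
#' over the period by construction.
#'
#' @param yearly A yearly [monthly_stack()] (one layer per year).
#' @param mask Optional logical matrix of pixels to include.
#' @return Data frame `year, value, anomaly`.
#' @export
regional_mean_series <- function(yearly, mask = NULL) {
  vals <- vapply(seq_along(yearly$year), function(i) {
    m <- yearly$values[, , i]
    if (!is.null(mask)) m <- m[mask]
    mean(m, na.rm = TRUE)
  }, numeric(1))
  data.frame(year = yearly$year, value = vals, anomaly = vals - mean(vals))
}

#' Linear trend of an annual series
#'
#' Ordinary least squares of value on year, with the two-tailed p-value of
#' the slope.
#'
#' @param year,value Numeric vectors (>= 3 points).
#' @return List `slope, intercept, r_squared, p_value`.
#' @export
linear_trend <- function(year, value) {
  if (length(year) < 3L) stop("linear_trend: need at least 3 points")
  fit <- stats::lm(value ~ year)
  s <- summary(fit)
  p <- if (nrow(s$coefficients) < 2L || s$coefficients[2, 2] == 0) NA_real_
       else s$coefficients[2, 4]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared, p_value = p)
}

#' Sample autocorrelation of an annual series
#'
#' Standard sample ACF with the usual white-noise 95% bounds
#' `+/- 1.96 / sqrt(n)`.
#'
#' @param value Numeric series.
#' @param max_lag Largest lag, default `n - 2`.
#' @return Data frame `lag, acf, lower, upper`.
#' @export
series_acf <- function(value, max_lag = length(value) - 2L) {
  n <- length(value)
  a <- stats::acf(value, lag.max = max_lag, plot = FALSE,
                  demean = TRUE, type = "correlation")
  bound <- 1.96 / sqrt(n)
  data.frame(lag = as.vector(a$lag), acf = as.vector(a$acf),
             lower = -bound, upper = bound)
}

#' Convert herd counts to standard sheep units
#'
#' One head of large livestock (cattle or horse) counts as five standard
#' sheep.
#'
#' @param cattle_horses Heads of large livestock.
#' @param sheep Heads of sheep.
#' @return Standard sheep units.
#' @export
livestock_to_standard_sheep <- function(cattle_horses, sheep) {
  if (any(cattle_horses < 0 | sheep < 0, na.rm = TRUE))
    stop("livestock_to_standard_sheep: counts must be >= 0")
  sheep + 5 * cattle_horses
}
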