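# Plot-level validation of modelled NPP against clip-plot biomass:
# biomass -> carbon conversion, extraction of accumulated model NPP at
# plot pixels, and the regression/error statistic suite.

#' Convert dry biomass to NPP carbon
#'
#' Total (above- plus below-ground) dry biomass times the carbon fraction
#' 0.475.
#'
#' @param agb,bgb Above- and below-ground dry biomass (g m-2), >= 0.
#' @param carbon_fraction Carbon fraction of dry matter, default 0.475.
#' @return NPP (gC m-2).
#' @export
biomass_to_npp <- function(agb, bgb, carbon_fraction = 0.475) {
  if (any(agb < 0 | bgb < 0, na.rm = TRUE))
    stop("biomass_to_npp: biomass must be >= 0")
  (agb + bgb) * carbon_fraction
}

#' Extract accumulated model NPP at plot locations
#'
#' For each plot, sums the modelled monthly NPP of the plot's year from
#' January through `through_month` at the pixel containing the plot.
#' January and February contribute nothing under the winter-zero rule, so
#' `through_month = 7` matches a July biomass survey and
#' `through_month = 12` gives the annual total.
#'
#' @param npp Monthly NPP [monthly_stack()].
#' @param plots Data frame with `x, y, year` (and optionally `agb, bgb`).
#' @param through_month Last month included (1..12), default 7.
#' @param carbon_fraction Passed to [biomass_to_npp()] when the plot table
#'   carries biomass columns.
#' @return The plot table with `estimated_npp` (and, if biomass columns
#'   are present, `observed_npp`) appended.
#' @export
extract_estimates <- function(npp, plots, through_month = 7L,
                              carbon_fraction = 0.475) {
  stopifnot(inherits(npp, "monthly_stack"))
  through_month <- as.integer(through_month)
  if (through_month < 1L || through_month > 12L)
    stop("extract_estimates: 'through_month' must be in 1..12")
  cell <- locate_pixel(npp$grid, plots$x, plots$y)
  est <- numeric(nrow(plots))
  for (i in seq_len(nrow(plots))) {
    sel <- npp$year == plots$year[i] & npp$month <= through_month
    if (!any(sel))
      stop(sprintf("extract_estimates: no NPP layers for year %d",
                   plots$year[i]))
    est[i] <- sum(npp$values[cell$row[i], cell$col[i], sel])
  }
  out <- plots
  out$estimated_npp <- est
  if (all(c("agb", "bgb") %in% names(plots)))
    out$observed_npp <- biomass_to_npp(plots$agb, plots$bgb, carbon_fraction)
  out
}

#' Validation statistic suite
#'
#' OLS regression of estimated on observed NPP (estimated on the y axis),
#' with t-tests on both coefficients, the regression F-test,
#' `RMSE = sqrt(mean((P - O)^2))` and `bias = mean(O - P)` — the
#' observed-minus-estimated convention, so a negative bias means the model
#' runs slightly high.
#'
#' @param observed,estimated Paired NPP values (gC m-2), n >= 3.
#' @return List `n, slope, intercept, slope_p, intercept_p, r_squared,
#'   f_statistic, f_p, rmse, bias`.
#' @export
validation_stats <- function(observed, estimated) {
  n <- length(observed)
  if (n < 3L || length(estimated) != n)
    stop("validation_stats: need >= 3 paired observations")
  if (any(!is.finite(observed)) || any(!is.finite(estimated)))
    stop("validation_stats: values must be finite")
  if (stats::var(observed) == 0)
    stop("validation_stats: observed values have zero variance")
  fit <- stats::lm(estimated ~ observed)
  s <- summary(fit)
  fstat <- s$fstatistic
  list(n = n,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_p = s$coefficients[2, 4],
       intercept_p = s$coefficients[1, 4],
       r_squared = s$r.squared,
       f_statistic = unname(fstat[1]),
       f_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                              lower.tail = FALSE)),
       rmse = sqrt(mean((estimated - observed)^2)),
       bias = mean(observed - estimated))
}
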