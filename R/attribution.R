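# Pixel-wise and county-wise climate attribution: Pearson correlation and
# first-order partial correlation of NPP with precipitation and
# temperature, with two-tailed t-test significance.

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric series, n >= 3, both with nonzero
#'   variance (`NA` returned otherwise, mirroring per-pixel nodata).
#' @return Correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("pearson_r: need equal-length series of >= 3 values")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' First-order partial correlation
#'
#' Correlation between X1 and X2 with X3 controlled:
#' `Rp = (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))`.
#' A control collinear with either variable (`|r13| = 1` or `|r23| = 1`,
#' to within floating-point resolution) yields `NA`: there is no residual
#' variation left to correlate.
#'
#' @param r12,r13,r23 Pairwise Pearson coefficients.
#' @return Partial correlation, clamped to `[-1, 1]` against rounding.
#' @export
partial_r <- function(r12, r13, r23) {
  out <- (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
  out[abs(r13) >= 1 - 1e-12 | abs(r23) >= 1 - 1e-12] <- NA_real_
  pmin(pmax(out, -1), 1)
}

r_p_value <- function(r, n, k) {
  df <- n - k
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(t), df, lower.tail = FALSE)
}

#' Per-pixel correlation (or partial-correlation) map
#'
#' Correlates the yearly NPP series of every pixel with the matching
#' climate series; with a control stack, computes the first-order partial
#' correlation via the three pairwise coefficients. Significance is a
#' per-pixel two-tailed t-test, `t = r * sqrt((n - k)/(1 - r^2))` with
#' `k = 2` (correlation) or `k = 3` (partial), uncorrected for multiple
#' testing (an FDR adjustment across pixels is available as an option).
#'
#' @param npp Yearly NPP [monthly_stack()] (one layer per year).
#' @param climate Matching yearly climate stack (same grid and years).
#' @param control Optional second climate stack to partial out.
#' @param mask Optional logical matrix of pixels to evaluate (e.g.
#'   vegetated pixels); others are nodata.
#' @param fdr If `TRUE`, Benjamini-Hochberg-adjust the p matrix across
#'   valid pixels.
#' @return Object of class `attribution_map`: list with matrices `r`, `p`,
#'   plus `n_years`, `kind` ("correlation"/"partial"), `target` and
#'   `controlled` labels, and the `grid`.
#' @export
correlation_map <- function(npp, climate, control = NULL, mask = NULL,
                            fdr = FALSE) {
  if (!grids_identical(npp$grid, climate$grid))
    stop_grid_mismatch(npp$grid, climate$grid, "'npp' and 'climate'")
  if (!identical(npp$year, climate$year))
    stop("correlation_map: 'npp' and 'climate' cover different years")
  n <- length(npp$year)
  k <- if (is.null(control)) 2L else 3L
  if (n < k + 1L)
    stop(sprintf("correlation_map: need at least %d years", k + 1L))
  rows <- npp$grid$rows; cols <- npp$grid$cols; npix <- rows * cols
  X <- matrix(npp$values, npix, n)     # pixel x year
  Y <- matrix(climate$values, npix, n)

  row_r <- function(A, B) {
    A <- A - rowMeans(A); B <- B - rowMeans(B)
    sa <- sqrt(rowSums(A^2)); sb <- sqrt(rowSums(B^2))
    out <- rowSums(A * B) / (sa * sb)
    out[sa == 0 | sb == 0] <- NA_real_
    pmin(pmax(out, -1), 1)
  }
  if (is.null(control)) {
    r <- row_r(X, Y)
  } else {
    if (!grids_identical(npp$grid, control$grid))
      stop_grid_mismatch(npp$grid, control$grid, "'npp' and 'control'")
    if (!identical(npp$year, control$year))
      stop("correlation_map: 'control' covers different years")
    Z <- matrix(control$values, npix, n)
    r <- partial_r(row_r(X, Y), row_r(X, Z), row_r(Y, Z))
  }
  if (!is.null(mask)) r[!as.vector(mask)] <- NA_real_
  p <- r_p_value(r, n, k)
  if (fdr) {
    ok <- !is.na(p)
    p[ok] <- stats::p.adjust(p[ok], method = "BH")
  }
  structure(list(r = matrix(r, rows, cols), p = matrix(p, rows, cols),
                 n_years = n,
                 kind = if (is.null(control)) "correlation" else "partial",
                 target = climate$variable,
                 controlled = if (is.null(control)) NA_character_
                              else control$variable,
                 grid = npp$grid),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %s of NPP ~ %s%s, n = %d years, %s\n",
              x$kind, x$target,
              if (!is.na(x$controlled)) paste0(" | ", x$controlled) else "",
              x$n_years, format(x$grid)))
  invisible(x)
}

#' Summarise an attribution map
#'
#' Fractions of valid pixels with positive / negative coefficients, the
#' fractions significant at 0.05 among each sign, the mean coefficient,
#' and a histogram of coefficients (default bin width 0.1 over [-1, 1]).
#'
#' @param map An [correlation_map()] result.
#' @param bin_width Histogram bin width.
#' @param alpha Significance level for the significant fractions.
#' @return List `n_valid, frac_positive, frac_negative, frac_sig_positive,
#'   frac_sig_negative, mean_r, median_abs_r, histogram` (data frame
#'   `lower, upper, count`).
#' @export
map_summary <- function(map, bin_width = 0.1, alpha = 0.05) {
  r <- as.vector(map$r); p <- as.vector(map$p)
  ok <- !is.na(r)
  r <- r[ok]; p <- p[ok]
  n <- length(r)
  breaks <- seq(-1, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- tabulate(cut(r, breaks, include.lowest = TRUE, labels = FALSE),
                     nbins = length(breaks) - 1L)
  list(n_valid = n,
       frac_positive = if (n) mean(r > 0) else NA_real_,
       frac_negative = if (n) mean(r < 0) else NA_real_,
       frac_sig_positive = if (n) mean(r > 0 & p < alpha) else NA_real_,
       frac_sig_negative = if (n) mean(r < 0 & p < alpha) else NA_real_,
       mean_r = if (n) mean(r) else NA_real_,
       median_abs_r = if (n) stats::median(abs(r)) else NA_real_,
       histogram = data.frame(lower = utils::head(breaks, -1),
                              upper = breaks[-1], count = counts))
}

sig_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' County-level seasonal correlation table
#'
#' Averages NPP and climate over each county first, then correlates the
#' county-mean yearly series: annual, spring, summer and autumn NPP
#' against the matching precipitation (seasonal sums) and mean temperature
#' (seasonal means). Columns follow the AP/AMT/SpP/SpMT/SuP/SuMT/AuP/AuMT
#' layout, with `*`/`**` flags at the two-tailed 0.05 and 0.01 levels.
#'
#' @param npp_monthly Monthly NPP [monthly_stack()].
#' @param precip_monthly,temp_monthly Monthly climate stacks (same grid).
#' @param counties Integer county-partition matrix
#'   (see [county_partition()]).
#' @param mask Optional logical matrix of pixels to include in county
#'   means (e.g. vegetated pixels).
#' @param seasons Season table, default [season_definition()].
#' @return Data frame: one row per county, coefficient columns
#'   `AP, AMT, SpP, SpMT, SuP, SuMT, AuP, AuMT` and matching `_sig` star
#'   columns.
#' @export
county_table <- function(npp_monthly, precip_monthly, temp_monthly,
                         counties, mask = NULL,
                         seasons = season_definition()) {
  ids <- sort(unique(as.vector(counties)))
  periods <- list(A = 1:12, Sp = seasons$spring, Su = seasons$summer,
                  Au = seasons$autumn)
  county_series <- function(stack, months, fun) {
    yearly <- climate_yearly(stack, months, fun)
    sapply(ids, function(cid) {
      sel <- counties == cid
      if (!is.null(mask)) sel <- sel & mask
      vapply(seq_along(yearly$year), function(i)
        mean(yearly$values[, , i][sel], na.rm = TRUE), numeric(1))
    })                                    # years x counties
  }
  out <- data.frame(county = ids)
  for (pn in names(periods)) {
    months <- periods[[pn]]
    npp_s <- county_series(npp_monthly, months, "sum")
    pr_s <- county_series(precip_monthly, months, "sum")
    tm_s <- county_series(temp_monthly, months, "mean")
    n <- nrow(npp_s)
    r_p <- vapply(seq_along(ids), function(j) pearson_r(npp_s[, j], pr_s[, j]),
                  numeric(1))
    r_t <- vapply(seq_along(ids), function(j) pearson_r(npp_s[, j], tm_s[, j]),
                  numeric(1))
    out[[paste0(pn, "P")]] <- r_p
    out[[paste0(pn, "P_sig")]] <- sig_stars(r_p_value(r_p, n, 2L))
    out[[paste0(pn, "MT")]] <- r_t
    out[[paste0(pn, "MT_sig")]] <- sig_stars(r_p_value(r_t, n, 2L))
  }
  out
}
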