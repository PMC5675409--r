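#' Define a common raster grid
#'
#' All gridded products in a pipeline run share a single grid: same pixel
#' counts, same origin, same pixel size. The convention is pixel centres,
#' row 1 = northernmost row, x increasing eastwards; `origin_x`/`origin_y`
#' give the map coordinates of the grid's top-left *corner*.
#'
#' @param rows,cols Positive pixel counts.
#' @param origin_x,origin_y Map coordinates (metres) of the top-left corner.
#' @param pixel_size Pixel edge length in map units (metres); must be > 0.
#' @param crs_id Free-text identifier of the coordinate system.
#' @param nodata Sentinel value used on disk for missing pixels. In memory
#'   missing pixels are `NA`; `nodata` never enters any statistic.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(rows, cols, origin_x = 0, origin_y = rows * pixel_size,
                        pixel_size = 500, crs_id = "local-metres",
                        nodata = -9999) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L)
    stop("raster_grid: 'rows' and 'cols' must be positive integers")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("raster_grid: 'pixel_size' must be > 0")
  structure(list(rows = rows, cols = cols,
                 origin_x = origin_x, origin_y = origin_y,
                 pixel_size = pixel_size, crs_id = crs_id,
                 nodata = nodata),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d pixels, %g m, origin (%g, %g), crs '%s'\n",
              x$rows, x$cols, x$pixel_size, x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' @export
format.raster_grid <- function(x, ...) {
  sprintf("%dx%d@%gm origin=(%g,%g)", x$rows, x$cols, x$pixel_size,
          x$origin_x, x$origin_y)
}

grids_identical <- function(a, b) {
  isTRUE(all.equal(a[c("rows", "cols", "origin_x", "origin_y", "pixel_size")],
                   b[c("rows", "cols", "origin_x", "origin_y", "pixel_size")],
                   tolerance = 1e-9))
}

stop_grid_mismatch <- function(a, b, what = "layers") {
  stop(sprintf("grid mismatch between %s: [%s] vs [%s]",
               what, format(a), format(b)), call. = FALSE)
}

#' Map coordinates of every pixel centre
#'
#' @param grid A [raster_grid()].
#' @return List with matrices `x` and `y` (rows x cols) of centre coordinates.
#' @export
pixel_centers <- function(grid) {
  xs <- grid$origin_x + (seq_len(grid$cols) - 0.5) * grid$pixel_size
  ys <- grid$origin_y - (seq_len(grid$rows) - 0.5) * grid$pixel_size
  list(x = matrix(xs, grid$rows, grid$cols, byrow = TRUE),
       y = matrix(ys, grid$rows, grid$cols))
}

#' Locate the pixel containing a point
#'
#' @param grid A [raster_grid()].
#' @param x,y Point coordinates (map units), vectorised.
#' @return Data frame with integer columns `row`, `col` (1-based).
#'   Points outside the grid raise an error.
#' @export
locate_pixel <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$pixel_size) + 1L
  row <- floor((grid$origin_y - y) / grid$pixel_size) + 1L
  bad <- col < 1L | col > grid$cols | row < 1L | row > grid$rows
  if (any(bad))
    stop(sprintf("point(s) outside grid [%s]: e.g. (%g, %g)",
                 format(grid), x[which(bad)[1]], y[which(bad)[1]]),
         call. = FALSE)
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Construct a monthly raster stack
#'
#' The in-memory container for every gridded monthly product: a
#' rows x cols x time array plus the grid and a (year, month) index.
#'
#' @param values Numeric array `rows x cols x n` (or a matrix for `n = 1`).
#' @param grid The shared [raster_grid()].
#' @param year,month Integer vectors of length `n` labelling each layer.
#' @param variable,units Names recorded for reporting.
#' @return An object of class `monthly_stack`.
#' @export
monthly_stack <- function(values, grid, year, month, variable = "value",
                          units = "") {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (length(dim(values)) != 3L)
    stop("monthly_stack: 'values' must be a rows x cols x time array")
  if (dim(values)[1] != grid$rows || dim(values)[2] != grid$cols)
    stop(sprintf("monthly_stack: array is %d x %d but grid is %d x %d",
                 dim(values)[1], dim(values)[2], grid$rows, grid$cols))
  n <- dim(values)[3]
  year <- as.integer(rep_len(year, n)); month <- as.integer(rep_len(month, n))
  if (any(month < 1L | month > 12L))
    stop("monthly_stack: 'month' must be in 1..12")
  structure(list(values = values, grid = grid, year = year, month = month,
                 variable = variable, units = units),
            class = "monthly_stack")
}

#' @export
print.monthly_stack <- function(x, ...) {
  cat(sprintf("<monthly_stack> '%s' [%s], %d layers (%d-%02d .. %d-%02d), grid %s\n",
              x$variable, x$units, length(x$year),
              x$year[1], x$month[1],
              x$year[length(x$year)], x$month[length(x$month)],
              format(x$grid)))
  invisible(x)
}

#' Select layers of a monthly stack
#'
#' @param stack A [monthly_stack()].
#' @param year,month Optional filters (vectors of accepted values).
#' @return A `monthly_stack` with the matching layers, in stored order.
#' @export
stack_subset <- function(stack, year = NULL, month = NULL) {
  keep <- rep(TRUE, length(stack$year))
  if (!is.null(year)) keep <- keep & stack$year %in% year
  if (!is.null(month)) keep <- keep & stack$month %in% month
  if (!any(keep)) stop("stack_subset: no layers match the selection")
  monthly_stack(stack$values[, , keep, drop = FALSE], stack$grid,
                stack$year[keep], stack$month[keep],
                stack$variable, stack$units)
}

layer_index <- function(stack, year, month) {
  i <- which(stack$year == year & stack$month == month)
  if (length(i) != 1L)
    stop(sprintf("stack '%s': expected exactly one layer for %d-%02d, found %d",
                 stack$variable, year, month, length(i)))
  i
}

check_complete_months <- function(stack) {
  want <- expand.grid(month = 1:12, year = sort(unique(stack$year)))
  have <- paste(stack$year, stack$month)
  gaps <- with(want, paste(year, month))[!with(want, paste(year, month)) %in% have]
  if (length(gaps))
    stop(sprintf("stack '%s' is missing %d year-months: %s", stack$variable,
                 length(gaps), paste(utils::head(gaps, 6), collapse = ", ")),
         call. = FALSE)
  invisible(stack)
}

# ---- ESRI ASCII grid I/O --------------------------------------------------
# Plain-text raster interchange (ncols/nrows/xllcorner/yllcorner/cellsize/
# nodata_value header + row-major values, northernmost row first).

#' Write one raster layer as an ESRI ASCII grid
#'
#' @param values Numeric matrix (rows x cols); `NA` written as the grid's
#'   nodata value.
#' @param grid The [raster_grid()] describing georeferencing.
#' @param path Output file path (conventionally `.asc`).
#' @param digits Significant digits retained (values round-trip at this
#'   precision; 15 keeps full double precision for practical purposes).
#' @export
write_ascii_grid <- function(values, grid, path, digits = 15) {
  if (!is.matrix(values) || nrow(values) != grid$rows || ncol(values) != grid$cols)
    stop(sprintf("write_ascii_grid: matrix %s does not match grid [%s]",
                 paste(dim(values), collapse = "x"), format(grid)))
  v <- values
  v[!is.finite(v)] <- grid$nodata
  hdr <- c(sprintf("ncols %d", grid$cols),
           sprintf("nrows %d", grid$rows),
           sprintf("xllcorner %.10g", grid$origin_x),
           sprintf("yllcorner %.10g", grid$origin_y - grid$rows * grid$pixel_size),
           sprintf("cellsize %.10g", grid$pixel_size),
           sprintf("nodata_value %.10g", grid$nodata))
  body <- apply(v, 1, function(r) paste(formatC(r, digits = digits, format = "g"),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any conforming .asc).
#' @param crs_id Coordinate system label to attach (not stored in the format).
#' @return List with `values` (matrix, nodata as `NA`) and `grid`.
#' @export
read_ascii_grid <- function(path, crs_id = "local-metres") {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr)))
    stop(sprintf("malformed ASCII grid header in %s", path))
  rows <- as.integer(hdr$nrows); cols <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != rows * cols)
    stop(sprintf("%s: expected %d values, found %d", path, rows * cols, length(vals)))
  m <- matrix(vals, rows, cols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  grid <- raster_grid(rows, cols, origin_x = hdr$xllcorner,
                      origin_y = hdr$yllcorner + rows * hdr$cellsize,
                      pixel_size = hdr$cellsize, crs_id = crs_id,
                      nodata = hdr$nodata_value)
  list(values = m, grid = grid)
}

#' Write a monthly stack as one ASCII grid per layer
#'
#' Files are named `<prefix>_<year>_<mm>.asc` inside `dir`.
#'
#' @param stack A [monthly_stack()].
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix, default the stack's variable name.
#' @return Invisibly, the vector of paths written.
#' @export
write_raster_stack <- function(stack, dir, prefix = stack$variable) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(stack$year))
  for (i in seq_along(stack$year)) {
    paths[i] <- file.path(dir, sprintf("%s_%d_%02d.asc", prefix,
                                       stack$year[i], stack$month[i]))
    write_ascii_grid(stack$values[, , i], stack$grid, paths[i])
  }
  invisible(paths)
}

#' Read a set of ASCII grids into a monthly stack
#'
#' Layer year/month are parsed from file names of the form
#' `<prefix>_<year>_<mm>.asc`. All layers must share one grid; a mismatch is
#' a hard error naming both grids.
#'
#' @param paths Character vector of `.asc` paths.
#' @param variable,units Stack labels.
#' @return A [monthly_stack()] ordered by (year, month).
#' @export
read_raster_stack <- function(paths, variable = "value", units = "") {
  if (!length(paths)) stop("read_raster_stack: no paths given")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("missing input raster(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  parse_ym <- function(p) {
    m <- regmatches(basename(p),
                    regexec("_([0-9]{1,4})_([0-9]{2})\\.asc$", basename(p)))[[1]]
    if (length(m) != 3)
      stop(sprintf("cannot parse year/month from file name: %s", basename(p)))
    as.integer(m[2:3])
  }
  ym <- t(vapply(paths, parse_ym, integer(2)))
  o <- order(ym[, 1], ym[, 2])
  paths <- paths[o]; ym <- ym[o, , drop = FALSE]
  first <- read_ascii_grid(paths[1])
  arr <- array(NA_real_, c(first$grid$rows, first$grid$cols, length(paths)))
  arr[, , 1] <- first$values
  if (length(paths) > 1) for (i in 2:length(paths)) {
    r <- read_ascii_grid(paths[i])
    if (!grids_identical(r$grid, first$grid))
      stop_grid_mismatch(first$grid, r$grid,
                         sprintf("'%s' and '%s'", basename(paths[1]), basename(paths[i])))
    arr[, , i] <- r$values
  }
  monthly_stack(arr, first$grid, ym[, 1], ym[, 2], variable, units)
}

# ---- station tables -------------------------------------------------------

#' Read monthly station meteorology from CSV
#'
#' Expects the header
#' `station_id,x,y,year,month,temp_c,precip_mm,sunshine_h`. Records are
#' validated: precipitation must be >= 0 and sunshine within 0..744 h.
#'
#' @param path CSV file path.
#' @return Data frame of station records.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop(sprintf("station file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "x", "y", "year", "month", "temp_c", "precip_mm",
            "sunshine_h")
  if (!all(need %in% names(df)))
    stop(sprintf("station file %s lacks column(s): %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  validate_stations(df)
}

validate_stations <- function(df) {
  if (any(df$precip_mm < 0, na.rm = TRUE))
    stop("station records invalid: negative precipitation", call. = FALSE)
  if (any(df$sunshine_h < 0 | df$sunshine_h > 744, na.rm = TRUE))
    stop("station records invalid: sunshine hours outside [0, 744]",
         call. = FALSE)
  if (any(df$month < 1 | df$month > 12))
    stop("station records invalid: month outside 1..12", call. = FALSE)
  df
}

#' Write station records to CSV
#'
#' @param stations Data frame as returned by [read_stations()].
#' @param path Output path.
#' @export
write_stations <- function(stations, path) {
  utils::write.csv(stations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
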