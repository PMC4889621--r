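#' Define a geographic grid
#'
#' A `grid_spec` fixes the geometry shared by all rasters in a workflow:
#' square cells in geographic degrees, row 1 at the northern edge, pixels
#' interpreted as areas. Cell `(r, c)` covers the half-open box
#' \eqn{[lon_0 + (c-1)s, lon_0 + c s) \times (lat_0 - r s, lat_0 - (r-1)s]}
#' so every point on the grid belongs to exactly one cell.
#'
#' @param origin_lon Longitude of the grid's north-west corner (degrees).
#' @param origin_lat Latitude of the grid's north-west corner (degrees).
#' @param cell_size Cell edge length in degrees; must be positive.
#' @param n_rows,n_cols Grid dimensions; at least 1 each.
#' @return An object of class `grid_spec`.
#' @examples
#' spec <- grid_spec(-111, 45, 0.004, 40, 40)
#' cell_centers(spec)[1:3, ]
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size, n_rows, n_cols) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L)
  structure(
    list(
      origin_lon = as.numeric(origin_lon),
      origin_lat = as.numeric(origin_lat),
      cell_size = as.numeric(cell_size),
      n_rows = n_rows,
      n_cols = n_cols
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells of %g deg, NW corner (%g, %g)\n",
    x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat
  ))
  invisible(x)
}

#' Compare two grid specs
#'
#' Specs read back from files carry floating-point noise in their
#' geotransform, so equality is tested to a tolerance (default 1e-9 degrees)
#' rather than bitwise.
#'
#' @param a,b `grid_spec` objects.
#' @param tol Absolute tolerance in degrees for origin and cell size.
#' @return `TRUE` if dimensions match exactly and geometry matches within `tol`.
#' @export
same_spec <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$origin_lon - b$origin_lon) <= tol &&
    abs(a$origin_lat - b$origin_lat) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol
}

#' Cell-center coordinates of a grid
#'
#' @param spec A `grid_spec`.
#' @return A tibble with `row`, `col`, `lon`, `lat` for every cell, in
#'   row-major order (row 1 first).
#' @export
cell_centers <- function(spec) {
  r <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  c <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  tibble::tibble(
    row = r,
    col = c,
    lon = spec$origin_lon + (c - 0.5) * spec$cell_size,
    lat = spec$origin_lat - (r - 0.5) * spec$cell_size
  )
}

#' Locate points on a grid
#'
#' Maps points to the (row, col) of the cell containing them under the
#' half-open cell convention (west/north edges inclusive).
#'
#' @param spec A `grid_spec`.
#' @param lon,lat Numeric vectors of coordinates.
#' @return A tibble with `row` and `col`; `NA` where the point falls outside
#'   the grid.
#' @export
locate_cells <- function(spec, lon, lat) {
  col <- floor((lon - spec$origin_lon) / spec$cell_size) + 1
  row <- floor((spec$origin_lat - lat) / spec$cell_size) + 1
  # north edge of row 1 is inclusive: lat == origin_lat gives row 1 already;
  # points exactly on an interior row boundary belong to the cell below,
  # which floor() delivers
  bad <- row < 1 | row > spec$n_rows | col < 1 | col > spec$n_cols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Construct a raster
#'
#' A `raster_grid` couples a numeric matrix to a [grid_spec()]. Missing
#' values are stored as `NA` internally so they never take part in
#' arithmetic; the `nodata` field records the sentinel used on disk.
#'
#' @param values Numeric matrix, `n_rows x n_cols`.
#' @param spec A `grid_spec` matching `dim(values)`.
#' @param nodata Sentinel written to / read from files (default -9999).
#' @param units Free-text unit label.
#' @return A `raster_grid`.
#' @export
raster_grid <- function(values, spec, nodata = -9999, units = "") {
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$n_rows, spec$n_cols))) {
    stop(sprintf(
      "values are %d x %d but spec declares %d x %d",
      nrow(values), ncol(values), spec$n_rows, spec$n_cols
    ))
  }
  storage.mode(values) <- "double"
  structure(
    list(values = values, spec = spec, nodata = nodata, units = units),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(
    "<raster_grid> %d x %d [%s]  range %s  NA cells %d\n",
    x$spec$n_rows, x$spec$n_cols, x$units,
    if (length(v)) sprintf("[%g, %g]", min(v), max(v)) else "(empty)",
    sum(is.na(x$values))
  ))
  invisible(x)
}

#' Constant-valued raster on a spec
#'
#' @param spec A `grid_spec`.
#' @param value Fill value (default `NA`).
#' @inheritParams raster_grid
#' @return A `raster_grid`.
#' @export
raster_fill <- function(spec, value = NA_real_, nodata = -9999, units = "") {
  raster_grid(
    matrix(value, spec$n_rows, spec$n_cols),
    spec,
    nodata = nodata, units = units
  )
}

#' Values of a raster at point locations
#'
#' @param raster A `raster_grid`.
#' @param lon,lat Coordinates of query points.
#' @return Numeric vector; `NA` outside the grid or over nodata cells.
#' @export
raster_extract <- function(raster, lon, lat) {
  idx <- locate_cells(raster$spec, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(idx$row)
  out[ok] <- raster$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Long-format view of a raster
#'
#' @param x A `raster_grid`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `lon`, `lat`, `value`.
#' @export
as_tibble.raster_grid <- function(x, ...) {
  out <- cell_centers(x$spec)
  out$value <- as.vector(t(x$values))
  out
}
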