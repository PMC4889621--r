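#' Read a raster from an ESRI ASCII grid file
#'
#' The package exchanges rasters as ESRI ASCII grids (`.asc`): a plain-text,
#' single-band, self-describing format carrying grid origin, cell size and
#' the nodata sentinel in its header. Values equal to the file's
#' `NODATA_value` are mapped to `NA` on read; the sentinel itself is kept in
#' the returned raster's `nodata` field and written back by
#' [write_raster()], so a write/read cycle is lossless.
#'
#' @param path Path to an existing `.asc` file.
#' @param units Optional unit label to attach (the format stores none).
#' @return A [raster_grid()].
#' @seealso [write_raster()], [resample_nearest()]
#' @export
read_raster <- function(path, units = "") {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed ASCII grid header line: ", ln)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop(
      "ASCII grid header incomplete; missing: ",
      paste(setdiff(need, names(hdr)), collapse = ", ")
    )
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  vals <- scan(path, what = double(), skip = length(lines), quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop(sprintf(
      "expected %d values, found %d in %s",
      n_rows * n_cols, length(vals), path
    ))
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  spec <- grid_spec(
    origin_lon = hdr$xllcorner,
    origin_lat = hdr$yllcorner + n_rows * hdr$cellsize,
    cell_size = hdr$cellsize,
    n_rows = n_rows, n_cols = n_cols
  )
  raster_grid(m, spec, nodata = nodata, units = units)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written with 17 significant digits, enough to round-trip
#' double precision exactly; `NA` cells are written as the raster's nodata
#' sentinel.
#'
#' @param raster A [raster_grid()].
#' @param path Output path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  spec <- raster$spec
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(c(
    paste("ncols", spec$n_cols),
    paste("nrows", spec$n_rows),
    paste("xllcorner", sprintf("%.17g", spec$origin_lon)),
    paste("yllcorner", sprintf("%.17g", spec$origin_lat - spec$n_rows * spec$cell_size)),
    paste("cellsize", sprintf("%.17g", spec$cell_size)),
    paste("NODATA_value", sprintf("%.17g", raster$nodata))
  ), con)
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  writeLines(
    apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = " ")),
    con
  )
  invisible(path)
}

#' Nearest-neighbour resampling onto a new grid
#'
#' Each target cell takes the value of the source cell that contains the
#' target cell's center; target cells whose centers fall outside the source
#' extent, or over source nodata, become `NA`. This is the kernel applied to
#' both categorical and scalar inputs when bringing them onto the model
#' grid.
#'
#' @param raster Source [raster_grid()].
#' @param target_spec A [grid_spec()] overlapping the source extent.
#' @return A `raster_grid` on `target_spec`.
#' @export
resample_nearest <- function(raster, target_spec) {
  src <- raster$spec
  if (same_spec(src, target_spec)) {
    return(raster_grid(raster$values, target_spec,
      nodata = raster$nodata, units = raster$units
    ))
  }
  src_w <- src$origin_lon
  src_e <- src$origin_lon + src$n_cols * src$cell_size
  src_s <- src$origin_lat - src$n_rows * src$cell_size
  src_n <- src$origin_lat
  tgt_w <- target_spec$origin_lon
  tgt_e <- target_spec$origin_lon + target_spec$n_cols * target_spec$cell_size
  tgt_s <- target_spec$origin_lat - target_spec$n_rows * target_spec$cell_size
  tgt_n <- target_spec$origin_lat
  if (tgt_w >= src_e || tgt_e <= src_w || tgt_s >= src_n || tgt_n <= src_s) {
    stop("source and target extents are disjoint; nothing to resample")
  }
  cx <- target_spec$origin_lon + (seq_len(target_spec$n_cols) - 0.5) * target_spec$cell_size
  cy <- target_spec$origin_lat - (seq_len(target_spec$n_rows) - 0.5) * target_spec$cell_size
  sc <- floor((cx - src$origin_lon) / src$cell_size) + 1
  sr <- floor((src$origin_lat - cy) / src$cell_size) + 1
  sc[sc < 1 | sc > src$n_cols] <- NA_integer_
  sr[sr < 1 | sr > src$n_rows] <- NA_integer_
  out <- matrix(NA_real_, target_spec$n_rows, target_spec$n_cols)
  ok_r <- which(!is.na(sr))
  ok_c <- which(!is.na(sc))
  if (length(ok_r) && length(ok_c)) {
    out[ok_r, ok_c] <- raster$values[sr[ok_r], sc[ok_c], drop = FALSE]
  }
  raster_grid(out, target_spec, nodata = raster$nodata, units = raster$units)
}
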