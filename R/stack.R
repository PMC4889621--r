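#' Monthly raster stack
#'
#' A `monthly_stack` holds one raster layer per calendar month over a
#' contiguous span (no gaps, strictly increasing), all on a shared
#' [grid_spec()]. It is the container for every time-varying input and
#' output: vegetation-index imagery, climate forcing, and NPP.
#'
#' @param values 3-D numeric array `n_rows x n_cols x n_months`, or a list
#'   of matrices/[raster_grid()]s in calendar order.
#' @param spec The shared `grid_spec`.
#' @param years,months Integer vectors keying each layer; must be a
#'   contiguous calendar sequence.
#' @param units Free-text unit label.
#' @return A `monthly_stack`.
#' @export
monthly_stack <- function(values, spec, years, months, units = "") {
  if (is.list(values)) {
    values <- vapply(
      values,
      function(v) if (inherits(v, "raster_grid")) v$values else as.matrix(v),
      matrix(0, spec$n_rows, spec$n_cols)
    )
  }
  stopifnot(length(dim(values)) == 3L)
  years <- as.integer(years)
  months <- as.integer(months)
  n <- dim(values)[3L]
  stopifnot(length(years) == n, length(months) == n, all(months %in% 1:12))
  if (dim(values)[1L] != spec$n_rows || dim(values)[2L] != spec$n_cols) {
    stop("layer dimensions do not match spec")
  }
  key <- years * 12L + (months - 1L)
  if (n > 1L && any(diff(key) != 1L)) {
    stop("months must be contiguous and strictly increasing in calendar order")
  }
  dimnames(values) <- list(NULL, NULL, sprintf("%04d-%02d", years, months))
  structure(
    list(values = values, spec = spec, years = years, months = months,
         units = units),
    class = "monthly_stack"
  )
}

#' @export
print.monthly_stack <- function(x, ...) {
  n <- length(x$years)
  cat(sprintf(
    "<monthly_stack> %d x %d x %d months [%s], %04d-%02d .. %04d-%02d\n",
    x$spec$n_rows, x$spec$n_cols, n, x$units,
    x$years[1], x$months[1], x$years[n], x$months[n]
  ))
  invisible(x)
}

#' Number of layers in a stack
#' @param stack A `monthly_stack`.
#' @return Integer month count.
#' @export
n_months <- function(stack) length(stack$years)

#' Extract one month as a raster
#'
#' @param stack A `monthly_stack`.
#' @param year,month Calendar key of the layer.
#' @return A [raster_grid()].
#' @export
stack_month <- function(stack, year, month) {
  i <- which(stack$years == year & stack$months == month)
  if (length(i) != 1L) stop(sprintf("month %04d-%02d not in stack", year, month))
  raster_grid(stack$values[, , i], stack$spec, units = stack$units)
}

#' Apply a function layerwise over one or more aligned stacks
#'
#' @param f Function of one matrix per stack argument, returning a matrix.
#' @param ... One or more `monthly_stack`s sharing spec and calendar span.
#' @param units Unit label of the result.
#' @return A `monthly_stack`.
#' @export
stack_map <- function(f, ..., units = "") {
  stacks <- list(...)
  s1 <- stacks[[1L]]
  for (s in stacks[-1L]) {
    if (!same_spec(s$spec, s1$spec) || !identical(s$years, s1$years) ||
        !identical(s$months, s1$months)) {
      stop("stacks are not aligned in space and time")
    }
  }
  out <- s1$values
  for (i in seq_len(dim(out)[3L])) {
    out[, , i] <- do.call(f, lapply(stacks, function(s) s$values[, , i]))
  }
  monthly_stack(out, s1$spec, s1$years, s1$months, units = units)
}

#' Restrict a stack to a calendar window
#'
#' @param stack A `monthly_stack`.
#' @param from_year,from_month First month kept.
#' @param to_year,to_month Last month kept.
#' @return A `monthly_stack` over the requested span.
#' @export
stack_window <- function(stack, from_year, from_month, to_year, to_month) {
  key <- stack$years * 12L + (stack$months - 1L)
  lo <- from_year * 12L + (from_month - 1L)
  hi <- to_year * 12L + (to_month - 1L)
  keep <- which(key >= lo & key <= hi)
  if (!length(keep)) stop("requested window is outside the stack span")
  monthly_stack(
    stack$values[, , keep, drop = FALSE], stack$spec,
    stack$years[keep], stack$months[keep], units = stack$units
  )
}

#' Annual sum of a monthly stack
#'
#' Convenience 12-month aggregation: sums complete calendar years only.
#'
#' @param stack A `monthly_stack`.
#' @return A named list of [raster_grid()]s, one per complete year.
#' @export
annual_sum <- function(stack) {
  out <- list()
  for (y in unique(stack$years)) {
    i <- which(stack$years == y)
    if (length(i) == 12L) {
      out[[as.character(y)]] <- raster_grid(
        apply(stack$values[, , i, drop = FALSE], c(1, 2), sum),
        stack$spec, units = stack$units
      )
    }
  }
  out
}

#' Monthly series of a stack at a point
#'
#' @param stack A `monthly_stack`.
#' @param lon,lat Point coordinates.
#' @return Tibble with `year`, `month`, `value`.
#' @export
stack_series <- function(stack, lon, lat) {
  idx <- locate_cells(stack$spec, lon, lat)
  if (is.na(idx$row[1])) stop("point is outside the stack extent")
  tibble::tibble(
    year = stack$years,
    month = stack$months,
    value = unname(stack$values[idx$row[1], idx$col[1], ])
  )
}
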