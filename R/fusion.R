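#' Land-cover class set
#'
#' @param class Character vector of unique class names.
#' @param code Integer codes, unique and non-negative, as stored in the
#'   categorical land-cover raster.
#' @return A tibble with columns `class` and `code`.
#' @export
cover_classes <- function(class, code) {
  code <- as.integer(code)
  stopifnot(
    length(class) == length(code),
    !anyDuplicated(class), !anyDuplicated(code), all(code >= 0L)
  )
  tibble::tibble(class = as.character(class), code = code)
}

#' Default general land-cover classes
#'
#' The ten aggregated classes used for continental NPP modelling: water,
#' evergreen forest, wetlands, lichen, mixed forest, woodlands, grasslands,
#' croplands, deciduous forest, brushland (codes 1--10). Any class set can
#' be supplied instead via [cover_classes()].
#'
#' @return A tibble with columns `class` and `code`.
#' @export
default_cover_classes <- function() {
  cover_classes(
    c(
      "water", "evergreen forest", "wetlands", "lichen", "mixed forest",
      "woodlands", "grasslands", "croplands", "deciduous forest", "brushland"
    ),
    1:10
  )
}

#' Aggregate fine land cover to per-class fractional cover
#'
#' For every coarse pixel, the fraction of class *k* is the count of valid
#' fine cells of class *k* whose centers fall inside that coarse pixel,
#' divided by the count of all valid fine cells there. Coarse pixels with no
#' valid fine coverage are nodata in every class.
#'
#' @param fine_lc Categorical [raster_grid()] of integer class codes; its
#'   cell size must be smaller than the coarse cell size and every non-`NA`
#'   code must appear in `classes`.
#' @param coarse_spec Target [grid_spec()] of the coarse (model) grid.
#' @param classes A [cover_classes()] tibble.
#' @return A `fractional_cover` object: `spec`, the `classes` tibble, and
#'   `fractions`, a named list of per-class fraction matrices in `[0, 1]`.
#' @export
aggregate_fractional_cover <- function(fine_lc, coarse_spec, classes) {
  fs <- fine_lc$spec
  if (fs$cell_size >= coarse_spec$cell_size) {
    stop("fine cell size must be smaller than the coarse cell size")
  }
  v <- fine_lc$values
  seen <- unique(v[!is.na(v)])
  unknown <- setdiff(seen, classes$code)
  if (length(unknown)) {
    stop(
      "fine land cover contains codes not in the class set: ",
      paste(sort(unknown), collapse = ", ")
    )
  }
  cx <- fs$origin_lon + (seq_len(fs$n_cols) - 0.5) * fs$cell_size
  cy <- fs$origin_lat - (seq_len(fs$n_rows) - 0.5) * fs$cell_size
  fc <- floor((cx - coarse_spec$origin_lon) / coarse_spec$cell_size) + 1
  fr <- floor((coarse_spec$origin_lat - cy) / coarse_spec$cell_size) + 1
  fc[fc < 1 | fc > coarse_spec$n_cols] <- NA_integer_
  fr[fr < 1 | fr > coarse_spec$n_rows] <- NA_integer_
  # linear index of the containing coarse cell for every fine cell
  li <- outer(fr, fc, function(r, c) (r - 1L) * coarse_spec$n_cols + c)
  inside <- !is.na(li)
  nb <- coarse_spec$n_rows * coarse_spec$n_cols
  valid_cells <- inside & !is.na(v)
  denom <- tabulate(li[valid_cells], nbins = nb)
  fractions <- lapply(classes$code, function(k) {
    cnt <- tabulate(li[valid_cells & !is.na(v) & v == k], nbins = nb)
    f <- cnt / denom
    f[denom == 0L] <- NA_real_
    matrix(f, coarse_spec$n_rows, coarse_spec$n_cols, byrow = TRUE)
  })
  names(fractions) <- classes$class
  structure(
    list(spec = coarse_spec, classes = classes, fractions = fractions),
    class = "fractional_cover"
  )
}

#' @export
print.fractional_cover <- function(x, ...) {
  cat(sprintf(
    "<fractional_cover> %d classes on a %d x %d grid\n",
    length(x$fractions), x$spec$n_rows, x$spec$n_cols
  ))
  invisible(x)
}

#' One class's fraction layer as a raster
#'
#' @param frac A `fractional_cover`.
#' @param class Class name.
#' @return A [raster_grid()].
#' @export
fraction_raster <- function(frac, class) {
  if (!class %in% names(frac$fractions)) stop("unknown class: ", class)
  raster_grid(frac$fractions[[class]], frac$spec, units = "fraction")
}

#' Identify pure coarse pixels per class
#'
#' A pure pixel holds at least `threshold` (default 0.9, i.e. 90 %) of a
#' single class; each is converted to a point at its pixel center. The
#' boundary is inclusive: a fraction of exactly `threshold` qualifies.
#' Classes with no pure pixels are reported with a warning and simply
#' contribute no rows; downstream code treats them as unavailable.
#'
#' @param frac A `fractional_cover`.
#' @param threshold Purity threshold in `(0, 1]`.
#' @return Tibble with `class`, `row`, `col`, `lon`, `lat`.
#' @export
identify_pure_pixels <- function(frac, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  spec <- frac$spec
  out <- purrr::map_dfr(names(frac$fractions), function(cl) {
    f <- frac$fractions[[cl]]
    hit <- which(!is.na(f) & f >= threshold, arr.ind = TRUE)
    tibble::tibble(
      class = cl,
      row = as.integer(hit[, 1]),
      col = as.integer(hit[, 2])
    )
  })
  empty <- setdiff(names(frac$fractions), unique(out$class))
  if (length(empty)) {
    warning(
      "no pure pixels at threshold ", threshold, " for: ",
      paste(empty, collapse = ", ")
    )
  }
  out$lon <- spec$origin_lon + (out$col - 0.5) * spec$cell_size
  out$lat <- spec$origin_lat - (out$row - 0.5) * spec$cell_size
  out
}

#' Sample a vegetation-index stack at pure-pixel points
#'
#' Extracts, for every point and month, the value of the coarse pixel
#' containing the point. Nodata months yield `NA` (missing), never zero.
#'
#' @param evi A [monthly_stack()] of vegetation-index values.
#' @param points Tibble with at least `class`, `lon`, `lat` (from
#'   [identify_pure_pixels()]).
#' @return Tibble with `class`, `lon`, `lat`, `year`, `month`, `evi` — one
#'   row per point-month.
#' @export
sample_evi_at_points <- function(evi, points) {
  idx <- locate_cells(evi$spec, points$lon, points$lat)
  if (anyNA(idx$row)) stop("some points fall outside the vegetation-index extent")
  n <- nrow(points)
  nt <- n_months(evi)
  flat <- matrix(evi$values, ncol = nt) # (row,col) major
  lin <- (idx$col - 1L) * evi$spec$n_rows + idx$row
  vals <- flat[lin, , drop = FALSE]
  tibble::tibble(
    class = rep(points$class, times = nt),
    lon = rep(points$lon, times = nt),
    lat = rep(points$lat, times = nt),
    year = rep(evi$years, each = n),
    month = rep(evi$months, each = n),
    evi = as.vector(vals)
  )
}

#' IDW interpolation parameters
#'
#' The variable search neighbourhood is realised as the `max_neighbors`
#' nearest sample points with no distance cut-off; distances are planar in
#' degrees on the model grid. `power` is used when `tune = FALSE` in
#' [build_ivi()]; otherwise the power minimising leave-one-out RMSPE over
#' `candidate_powers` is chosen per class.
#'
#' @param power Fixed inverse-distance exponent (> 0).
#' @param candidate_powers Powers searched during tuning.
#' @param max_neighbors Number of nearest samples used per prediction.
#' @return An `idw_params` list.
#' @export
idw_params <- function(power = 2,
                       candidate_powers = seq(1, 4, by = 0.5),
                       max_neighbors = 12L) {
  stopifnot(power > 0, length(candidate_powers) >= 1, max_neighbors >= 1)
  structure(
    list(
      power = power,
      candidate_powers = sort(as.numeric(candidate_powers)),
      max_neighbors = as.integer(max_neighbors)
    ),
    class = "idw_params"
  )
}

# Core IDW predictor. Predicts z at (tx, ty) from samples (sx, sy, sz)
# using the k nearest samples and weights d^(-power). Coincident samples
# (d < zero_tol) short-circuit to the mean sample value at that location:
# IDW is an exact interpolator.
idw_predict <- function(sx, sy, sz, tx, ty, power, k, zero_tol = 1e-12) {
  ok <- !is.na(sz)
  sx <- sx[ok]; sy <- sy[ok]; sz <- sz[ok]
  n <- length(sz)
  if (n < 1L) stop("IDW requires at least one valid sample")
  k <- min(k, n)
  d2 <- outer(tx, sx, "-")^2 + outer(ty, sy, "-")^2
  pred <- numeric(length(tx))
  for (i in seq_along(tx)) {
    di <- d2[i, ]
    hit <- di < zero_tol^2
    if (any(hit)) {
      pred[i] <- mean(sz[hit])
      next
    }
    nn <- if (k < n) order(di)[seq_len(k)] else seq_len(n)
    w <- di[nn]^(-power / 2) # d^-power with d2 = d^2
    pred[i] <- sum(w * sz[nn]) / sum(w)
  }
  pred
}

#' Leave-one-out RMSPE of IDW at a given power
#'
#' Each sample point is predicted from all remaining points of its class
#' and month; the root-mean-square prediction error measures how well that
#' power reconstructs the class's vegetation-index field.
#'
#' @param samples Tibble from [sample_evi_at_points()], a single class.
#' @param year,month Month whose values are cross-validated.
#' @param power Inverse-distance exponent.
#' @param max_neighbors Neighbourhood size (as in [idw_params()]).
#' @return Non-negative RMSPE.
#' @export
idw_rmspe <- function(samples, year, month, power, max_neighbors = 12L) {
  s <- samples[samples$year == year & samples$month == month & !is.na(samples$evi), ]
  n <- nrow(s)
  if (n < 2L) stop("leave-one-out cross-validation needs at least 2 valid points")
  err <- vapply(seq_len(n), function(i) {
    idw_predict(
      s$lon[-i], s$lat[-i], s$evi[-i], s$lon[i], s$lat[i],
      power, max_neighbors
    ) - s$evi[i]
  }, numeric(1))
  sqrt(mean(err^2))
}

#' Select the IDW power minimising leave-one-out RMSPE
#'
#' Ties are broken toward the smallest candidate power.
#'
#' @inheritParams idw_rmspe
#' @param candidate_powers Non-empty vector of powers to search.
#' @return The selected power.
#' @export
select_idw_power <- function(samples, year, month,
                             candidate_powers = seq(1, 4, by = 0.5),
                             max_neighbors = 12L) {
  stopifnot(length(candidate_powers) >= 1)
  cand <- sort(as.numeric(candidate_powers))
  rmspe <- vapply(
    cand,
    function(p) idw_rmspe(samples, year, month, p, max_neighbors),
    numeric(1)
  )
  cand[which.min(rmspe)] # first minimum = smallest power on ties
}

#' Interpolate one class-month onto a grid by IDW
#'
#' Produces the class's vegetation index over the full grid as if every
#' cell were pure, from the class's pure-pixel samples. Values are an exact
#' interpolation at sample locations and are clipped to the valid
#' vegetation-index range `[-0.2, 1]` elsewhere.
#'
#' @param samples Single-class tibble from [sample_evi_at_points()].
#' @param year,month Month to interpolate.
#' @param target_spec Output [grid_spec()].
#' @param params An [idw_params()] (its fixed `power` is used).
#' @return A [raster_grid()].
#' @export
idw_interpolate <- function(samples, year, month, target_spec,
                            params = idw_params()) {
  s <- samples[samples$year == year & samples$month == month & !is.na(samples$evi), ]
  if (nrow(s) == 0L) {
    stop(sprintf(
      "no valid samples for class '%s' in %04d-%02d",
      samples$class[1], year, month
    ))
  }
  ctr <- cell_centers(target_spec)
  z <- idw_predict(
    s$lon, s$lat, s$evi, ctr$lon, ctr$lat,
    params$power, params$max_neighbors
  )
  z <- pmin(pmax(z, -0.2), 1)
  raster_grid(
    matrix(z, target_spec$n_rows, target_spec$n_cols, byrow = TRUE),
    target_spec,
    units = "EVI"
  )
}

# Precomputed neighbour geometry shared across months of one class: the
# sample locations do not change month to month, so neighbour indices and
# unnormalised weights are built once per class and reused.
idw_plan <- function(sx, sy, tx, ty, power, k, zero_tol = 1e-12) {
  n <- length(sx)
  k <- min(k, n)
  d2 <- outer(tx, sx, "-")^2 + outer(ty, sy, "-")^2
  nn <- matrix(0L, length(tx), k)
  w <- matrix(0, length(tx), k)
  exact <- vector("list", length(tx))
  for (i in seq_along(tx)) {
    di <- d2[i, ]
    hit <- which(di < zero_tol^2)
    if (length(hit)) {
      exact[[i]] <- hit
      nn[i, ] <- 1L # placeholder; overwritten by the exact rule on apply
      w[i, 1L] <- 1
      next
    }
    o <- if (k < n) order(di)[seq_len(k)] else seq_len(n)
    nn[i, ] <- o
    w[i, ] <- di[o]^(-power / 2)
  }
  list(nn = nn, w = w, exact = exact)
}

idw_apply_plan <- function(plan, z) {
  zmat <- matrix(z[plan$nn], nrow = nrow(plan$nn))
  pred <- rowSums(plan$w * zmat) / rowSums(plan$w)
  for (i in which(!vapply(plan$exact, is.null, logical(1)))) {
    pred[i] <- mean(z[plan$exact[[i]]])
  }
  pred
}

#' Build per-class interpolated vegetation-index stacks
#'
#' Composes the fusion chain: pure-pixel identification, point sampling of
#' the vegetation-index stack, per-class power selection (leave-one-out
#' RMSPE on a representative month — the month with the class's highest
#' mean sampled value), and IDW interpolation of every month onto the
#' coarse grid. Classes with no pure pixels are flagged unavailable and
#' excluded downstream.
#'
#' @param evi A [monthly_stack()] of vegetation-index values on the coarse
#'   grid.
#' @param frac A `fractional_cover` on the same grid.
#' @param params An [idw_params()].
#' @param threshold Purity threshold passed to [identify_pure_pixels()].
#' @param tune If `TRUE` (default) select the power per class over
#'   `params$candidate_powers`; otherwise use `params$power` everywhere.
#' @return Named list of per-class `monthly_stack`s, with attributes
#'   `unavailable` (classes lacking pure pixels), `powers` (named vector of
#'   selected powers) and `pure_pixels` (the sample tibble).
#' @export
build_ivi <- function(evi, frac, params = idw_params(), threshold = 0.9,
                      tune = TRUE) {
  if (!same_spec(evi$spec, frac$spec)) {
    stop("vegetation-index stack and fractional cover are on different grids")
  }
  pts <- withCallingHandlers(
    identify_pure_pixels(frac, threshold),
    warning = function(w) invokeRestart("muffleWarning")
  )
  present <- intersect(names(frac$fractions), unique(pts$class))
  unavailable <- setdiff(names(frac$fractions), present)
  if (length(unavailable)) {
    warning(
      "classes without pure pixels are unavailable: ",
      paste(unavailable, collapse = ", ")
    )
  }
  samples <- sample_evi_at_points(evi, pts)
  ctr <- cell_centers(evi$spec)
  nt <- n_months(evi)
  powers <- stats::setNames(numeric(0), character(0))
  out <- list()
  for (cl in present) {
    s <- samples[samples$class == cl, ]
    means <- stats::aggregate(
      s$evi, list(year = s$year, month = s$month),
      mean, na.rm = TRUE
    )
    rep_i <- which.max(means$x)
    pw <- if (tune && sum(!is.na(s$evi[s$year == means$year[rep_i] &
                                         s$month == means$month[rep_i]])) >= 2) {
      select_idw_power(
        s, means$year[rep_i], means$month[rep_i],
        params$candidate_powers, params$max_neighbors
      )
    } else {
      params$power
    }
    powers[cl] <- pw
    pts_cl <- s[s$year == s$year[1] & s$month == s$month[1], ]
    plan <- idw_plan(
      pts_cl$lon, pts_cl$lat, ctr$lon, ctr$lat,
      pw, params$max_neighbors
    )
    arr <- array(NA_real_, c(evi$spec$n_rows, evi$spec$n_cols, nt))
    for (t in seq_len(nt)) {
      z <- s$evi[s$year == evi$years[t] & s$month == evi$months[t]]
      if (all(is.na(z))) next
      pred <- if (anyNA(z)) {
        ok <- !is.na(z)
        idw_predict(
          pts_cl$lon[ok], pts_cl$lat[ok], z[ok], ctr$lon, ctr$lat,
          pw, params$max_neighbors
        )
      } else {
        idw_apply_plan(plan, z)
      }
      arr[, , t] <- matrix(
        pmin(pmax(pred, -0.2), 1),
        evi$spec$n_rows, evi$spec$n_cols,
        byrow = TRUE
      )
    }
    out[[cl]] <- monthly_stack(arr, evi$spec, evi$years, evi$months,
                               units = "EVI")
  }
  attr(out, "unavailable") <- unavailable
  attr(out, "powers") <- powers
  attr(out, "pure_pixels") <- pts
  out
}
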