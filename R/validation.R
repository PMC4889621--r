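#' Tower flux records
#'
#' Monthly eddy-covariance records in a tidy schema: one row per
#' site-month. `gpp` is gross primary production in gC m-2 month-1;
#' `reco` (ecosystem respiration) is optional and carried through.
#'
#' @param df Data frame with columns `site_id`, `lon`, `lat`, `cover`,
#'   `year`, `month`, `gpp` (and optionally `reco`).
#' @return A validated tibble.
#' @export
tower_records <- function(df) {
  need <- c("site_id", "lon", "lat", "cover", "year", "month", "gpp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tower records missing columns: ",
                         paste(miss, collapse = ", "))
  df <- tibble::as_tibble(df)
  if (any(df$gpp < 0, na.rm = TRUE)) stop("gpp must be non-negative")
  if (any(!(df$month %in% 1:12))) stop("month must be in 1..12")
  dplyr::arrange(df, .data$site_id, .data$year, .data$month)
}

#' Read tower records from CSV
#'
#' @param path CSV with the [tower_records()] schema.
#' @return A tower-record tibble.
#' @export
read_tower_csv <- function(path) {
  tower_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Filter tower sites by record completeness
#'
#' Keeps sites with at least `min_years` distinct calendar years in which
#' all 12 months have a GPP value — full-year coverage is required so that
#' dormant-season behaviour enters the evaluation. Years with any missing
#' month do not count.
#'
#' @param records A [tower_records()] tibble.
#' @param min_years Minimum number of complete years (default 3).
#' @return The filtered tibble (possibly zero rows).
#' @export
filter_sites <- function(records, min_years = 3) {
  full_years <- records |>
    dplyr::filter(!is.na(.data$gpp)) |>
    dplyr::distinct(.data$site_id, .data$year, .data$month) |>
    dplyr::count(.data$site_id, .data$year, name = "n_months") |>
    dplyr::filter(.data$n_months == 12L) |>
    dplyr::count(.data$site_id, name = "n_full_years")
  keep <- full_years$site_id[full_years$n_full_years >= min_years]
  dplyr::filter(records, .data$site_id %in% keep)
}

#' Convert GPP to NPP by a fixed ratio
#'
#' Monthly NPP is taken as a fixed fraction of GPP; 0.40-0.50 brackets the
#' published uncertainty for temperate ecosystems (forest studies center
#' on 0.47).
#'
#' @param gpp GPP, gC m-2 month-1 (non-negative).
#' @param ratio NPP:GPP ratio in `(0, 1]`.
#' @return NPP, gC m-2 month-1.
#' @export
npp_from_gpp <- function(gpp, ratio = 0.40) {
  stopifnot(ratio > 0, ratio <= 1)
  if (any(gpp < 0, na.rm = TRUE)) stop("gpp must be non-negative")
  ratio * gpp
}

#' Extract a modelled NPP series at a tower location
#'
#' `point` mode returns the containing pixel's value per month; `mean3x3`
#' averages the valid cells of the 3 x 3 window centred on the containing
#' pixel (truncated at grid edges), emulating a tower footprint of roughly
#' nine model pixels.
#'
#' @param npp A [monthly_stack()] of modelled NPP.
#' @param lon,lat Tower coordinates (must fall inside the grid).
#' @param mode `"point"` or `"mean3x3"`.
#' @return Tibble with `year`, `month`, `npp_model`.
#' @export
extract_footprint <- function(npp, lon, lat, mode = c("point", "mean3x3")) {
  mode <- match.arg(mode)
  idx <- locate_cells(npp$spec, lon, lat)
  if (is.na(idx$row[1])) stop("tower location is outside the model grid")
  r <- idx$row[1]; c <- idx$col[1]
  if (mode == "point") {
    series <- npp$values[r, c, ]
  } else {
    rr <- max(1, r - 1):min(npp$spec$n_rows, r + 1)
    cc <- max(1, c - 1):min(npp$spec$n_cols, c + 1)
    series <- apply(
      npp$values[rr, cc, , drop = FALSE], 3L,
      function(w) if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
    )
  }
  tibble::tibble(year = npp$years, month = npp$months,
                 npp_model = unname(series))
}

#' Linear regression of measured on modelled NPP
#'
#' Ordinary least squares with measured (tower-derived) NPP as response
#' and modelled NPP as predictor. `r_squared` is the squared Pearson
#' correlation (orientation-free); `bias_pct` is
#' `100 (mean modelled - mean measured) / mean measured`, negative when
#' the model runs low. Zero variance in either series leaves `r_squared`
#' missing rather than zero.
#'
#' @param modeled,measured Paired numeric series; pairs with any missing
#'   value are dropped, and at least 3 complete pairs are required.
#' @return An object of class `npp_regression` with fields `r_squared`,
#'   `slope`, `intercept`, `n`, `bias_pct`, and the fitted pairs.
#' @export
regress_npp <- function(modeled, measured) {
  stopifnot(length(modeled) == length(measured))
  ok <- is.finite(modeled) & is.finite(measured)
  x <- modeled[ok]
  y <- measured[ok]
  n <- length(x)
  if (n < 3L) stop("regression needs at least 3 complete pairs")
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    r2 <- NA_real_; slope <- NA_real_; intercept <- NA_real_
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r2 <- stats::cor(x, y)^2
  }
  bias <- if (mean(y) != 0) 100 * (mean(x) - mean(y)) / mean(y) else NA_real_
  structure(
    list(
      r_squared = r2, slope = slope, intercept = intercept, n = n,
      bias_pct = bias, modeled = x, measured = y
    ),
    class = "npp_regression"
  )
}

#' @export
print.npp_regression <- function(x, ...) {
  cat(sprintf(
    "<npp_regression> n = %d, R^2 = %s, slope = %.3g, intercept = %.3g, bias = %.1f%%\n",
    x$n,
    ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
    x$slope, x$intercept, x$bias_pct
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an NPP regression
#'
#' @param x An `npp_regression`.
#' @param ... Unused.
#' @return One-row tibble of coefficients.
#' @export
tidy.npp_regression <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' One-row summary of an NPP regression
#'
#' @param x An `npp_regression`.
#' @param ... Unused.
#' @return Tibble with `r_squared`, `slope`, `intercept`, `n`, `bias_pct`.
#' @export
glance.npp_regression <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, slope = x$slope, intercept = x$intercept,
    n = x$n, bias_pct = x$bias_pct
  )
}

#' Default meteorological season map
#'
#' Winter = Dec-Feb, spring = Mar-May, summer = Jun-Aug, autumn = Sep-Nov.
#'
#' @return Named character vector of length 12 (month -> season).
#' @export
default_season_map <- function() {
  stats::setNames(
    c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
      "summer", "autumn", "autumn", "autumn", "winter"),
    1:12
  )
}

safe_glance <- function(modeled, measured) {
  out <- try(regress_npp(modeled, measured), silent = TRUE)
  if (inherits(out, "try-error")) {
    tibble::tibble(
      r_squared = NA_real_, slope = NA_real_, intercept = NA_real_,
      n = sum(is.finite(modeled) & is.finite(measured)),
      bias_pct = NA_real_
    )
  } else {
    glance(out)
  }
}

#' Grouped evaluation report
#'
#' Regresses measured on modelled NPP pooled and within each site, season
#' and land-cover group. Groups with fewer than 3 complete pairs are
#' reported with missing statistics rather than dropped.
#'
#' @param pairs Tibble with columns `site_id`, `cover`, `year`, `month`,
#'   `npp_model`, `npp_tower`.
#' @param season_map Month-to-season map as from [default_season_map()].
#' @return An `npp_eval_report`: list of tibbles `pooled`, `by_site`,
#'   `by_season`, `by_cover`, plus the tagged `pairs`.
#' @export
grouped_reports <- function(pairs, season_map = default_season_map()) {
  need <- c("site_id", "cover", "year", "month", "npp_model", "npp_tower")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("pairs missing columns: ", paste(miss, collapse = ", "))
  pairs <- dplyr::mutate(pairs, season = unname(season_map[as.character(.data$month)]))
  g <- function(d) safe_glance(d$npp_model, d$npp_tower)
  structure(
    list(
      pooled = g(pairs),
      by_site = pairs |>
        dplyr::group_by(.data$site_id, .data$cover) |>
        dplyr::group_modify(~ g(.x)) |>
        dplyr::ungroup(),
      by_season = pairs |>
        dplyr::group_by(.data$season) |>
        dplyr::group_modify(~ g(.x)) |>
        dplyr::ungroup(),
      by_cover = pairs |>
        dplyr::group_by(.data$cover) |>
        dplyr::group_modify(~ g(.x)) |>
        dplyr::ungroup(),
      pairs = pairs
    ),
    class = "npp_eval_report"
  )
}

#' @export
print.npp_eval_report <- function(x, ...) {
  cat("<npp_eval_report>\n  pooled: ")
  cat(sprintf(
    "R^2 = %.3f, n = %d, bias = %.1f%%\n",
    x$pooled$r_squared, x$pooled$n, x$pooled$bias_pct
  ))
  cat("  by season:\n")
  print(x$by_season)
  invisible(x)
}

#' Paired comparison of two NPP:GPP ratio choices
#'
#' Runs a paired t-test between the tower NPP series obtained under two
#' ratios. Note that rescaling one series by a constant cannot change the
#' Pearson correlation with the model, so evaluation R^2 is provably
#' identical under either ratio; this utility only quantifies the level
#' difference.
#'
#' @param gpp Tower GPP series.
#' @param ratio_a,ratio_b The two ratios compared (defaults 0.40, 0.50).
#' @return `htest` object from [stats::t.test()].
#' @export
ratio_ttest <- function(gpp, ratio_a = 0.40, ratio_b = 0.50) {
  stats::t.test(npp_from_gpp(gpp, ratio_a), npp_from_gpp(gpp, ratio_b),
                paired = TRUE)
}

#' Assemble model-tower pairs for evaluation
#'
#' Joins tower records (converted to NPP at `ratio`) with the model
#' composite extracted at each tower location.
#'
#' @param records [tower_records()] tibble (already site-filtered).
#' @param composite [monthly_stack()] of composite modelled NPP.
#' @param ratio NPP:GPP conversion ratio.
#' @param mode Footprint mode for [extract_footprint()].
#' @return Pairs tibble suitable for [grouped_reports()].
#' @export
make_eval_pairs <- function(records, composite, ratio = 0.40,
                            mode = c("point", "mean3x3")) {
  mode <- match.arg(mode)
  sites <- dplyr::distinct(records, .data$site_id, .data$lon, .data$lat,
                           .data$cover)
  extracted <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    dplyr::mutate(
      extract_footprint(composite, sites$lon[i], sites$lat[i], mode),
      site_id = sites$site_id[i]
    )
  })
  records |>
    dplyr::mutate(npp_tower = npp_from_gpp(.data$gpp, ratio)) |>
    dplyr::inner_join(extracted, by = c("site_id", "year", "month")) |>
    dplyr::select(
      "site_id", "cover", "year", "month", "npp_model", "npp_tower"
    )
}
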