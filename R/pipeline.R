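#' Run the full fusion + CASA pipeline
#'
#' The five processing steps in one call: (1) aggregate fine land cover to
#' fractional cover on the vegetation-index grid; (2-3) extract pure
#' pixels and build per-class interpolated vegetation-index stacks;
#' (3) run the CASA model independently per class; (4) weight each class's
#' NPP by its cover fraction; (5) sum to the composite NPP estimate.
#'
#' @param fine_lc Fine-resolution categorical land-cover [raster_grid()].
#' @param evi [monthly_stack()] of vegetation-index values on the coarse
#'   model grid; its span is the reporting span.
#' @param climate A [climate_inputs()] covering the reporting span plus,
#'   ideally, two preceding spin-up years.
#' @param soil Soil-texture code [raster_grid()] on the coarse grid (or a
#'   single code).
#' @param classes [cover_classes()] tibble.
#' @param idw [idw_params()] controlling the interpolation.
#' @param casa [casa_params()] controlling the ecosystem model.
#' @param threshold Pure-pixel threshold (default 0.9).
#' @param tune Select the IDW power per class by cross-validation.
#' @param rooting_multiplier Subsoil capacity multiplier (see
#'   [soil_capacity_grids()]).
#' @param renormalize Renormalise composite pixels whose contributing
#'   fraction falls short of 1.
#' @return List with `frac` (fractional cover), `ivi` (per-class stacks),
#'   `npp_by_class`, `composite` (monthly_stack), `coverage` raster,
#'   `diagnostics` (per-class CASA diagnostics) and `powers`.
#' @export
run_fusion_casa <- function(fine_lc, evi, climate, soil,
                            classes = default_cover_classes(),
                            idw = idw_params(), casa = casa_params(),
                            threshold = 0.9, tune = TRUE,
                            rooting_multiplier = 1, renormalize = TRUE) {
  frac <- aggregate_fractional_cover(fine_lc, evi$spec, classes)
  ivi <- suppressWarnings(
    build_ivi(evi, frac, params = idw, threshold = threshold, tune = tune)
  )
  if (!length(ivi)) stop("no class has pure pixels; cannot run the model")
  caps <- soil_capacity_grids(soil, rooting_multiplier = rooting_multiplier,
                              spec = evi$spec)
  runs <- lapply(ivi, run_casa_class, climate = climate, caps = caps,
                 params = casa)
  npp_by_class <- lapply(runs, `[[`, "npp")
  comp <- composite_npp(npp_by_class, frac, renormalize = renormalize)
  list(
    frac = frac,
    ivi = ivi,
    npp_by_class = npp_by_class,
    composite = comp$composite,
    coverage = comp$coverage,
    diagnostics = lapply(runs, `[[`, "diagnostics"),
    powers = attr(ivi, "powers")
  )
}

#' Evaluate a composite NPP stack against tower records
#'
#' Applies the site-completeness filter, converts tower GPP to NPP at
#' `ratio`, extracts the model at each site with the chosen footprint, and
#' returns pooled and grouped regression reports.
#'
#' @param composite [monthly_stack()] of composite modelled NPP.
#' @param records [tower_records()] tibble.
#' @param ratio NPP:GPP conversion ratio (default 0.40).
#' @param mode Footprint mode: `"point"` or `"mean3x3"`.
#' @param min_years Site filter threshold (default 3 complete years).
#' @param season_map Month-to-season map.
#' @return An `npp_eval_report` (see [grouped_reports()]).
#' @export
evaluate_against_towers <- function(composite, records, ratio = 0.40,
                                    mode = c("point", "mean3x3"),
                                    min_years = 3,
                                    season_map = default_season_map()) {
  mode <- match.arg(mode)
  kept <- filter_sites(records, min_years = min_years)
  if (!nrow(kept)) stop("no tower site passes the completeness filter")
  pairs <- make_eval_pairs(kept, composite, ratio = ratio, mode = mode)
  grouped_reports(pairs, season_map = season_map)
}
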