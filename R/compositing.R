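#' Scale a class's NPP stack by its fractional cover
#'
#' Elementwise product of the per-class NPP with that class's coverage
#' fraction; nodata in either operand propagates.
#'
#' @param npp_class [monthly_stack()] of per-class NPP.
#' @param fraction [raster_grid()] of the class's cover fraction in `[0, 1]`.
#' @return A `monthly_stack` of proportional NPP.
#' @export
weight_by_fraction <- function(npp_class, fraction) {
  if (!same_spec(npp_class$spec, fraction$spec)) {
    stop("NPP stack and fraction raster are on different grids")
  }
  out <- npp_class$values
  for (i in seq_len(dim(out)[3L])) {
    out[, , i] <- out[, , i] * fraction$values
  }
  monthly_stack(out, npp_class$spec, npp_class$years, npp_class$months,
                units = npp_class$units)
}

#' Composite per-class NPP into a total landscape estimate
#'
#' Sums the fraction-weighted per-class stacks pixelwise, so that only the
#' cover types present in a pixel influence its total. Where the
#' contributing fractions do not reach 1 (a class without pure pixels
#' contributes nothing), the sum is renormalised by the contributing
#' fraction — so partial class coverage does not bias the composite low —
#' and flagged in a coverage-diagnostic raster. Set `renormalize = FALSE`
#' to keep the raw partial sum.
#'
#' @param npp_by_class Named list of per-class NPP [monthly_stack()]s
#'   (unweighted — weighting happens here).
#' @param frac The `fractional_cover` used to weight each class.
#' @param renormalize Rescale by contributing fraction where it is < 1.
#' @param tol Shortfall below which no renormalisation is applied.
#' @return List with `composite` (monthly_stack), `coverage`
#'   ([raster_grid()] of the summed contributing fraction before
#'   renormalisation) and `classes_used`.
#' @export
composite_npp <- function(npp_by_class, frac, renormalize = TRUE,
                          tol = 1e-6) {
  if (!length(npp_by_class)) stop("no per-class NPP stacks supplied")
  used <- intersect(names(npp_by_class), names(frac$fractions))
  if (!length(used)) stop("class names do not match the fractional cover")
  s1 <- npp_by_class[[used[1]]]
  total <- array(0, dim(s1$values))
  coverage <- matrix(0, s1$spec$n_rows, s1$spec$n_cols)
  for (cl in used) {
    st <- npp_by_class[[cl]]
    if (!same_spec(st$spec, s1$spec) || !identical(st$years, s1$years)) {
      stop("per-class stacks are not aligned")
    }
    f <- frac$fractions[[cl]]
    f0 <- ifelse(is.na(f), 0, f)
    coverage <- coverage + f0
    for (i in seq_len(dim(total)[3L])) {
      contrib <- st$values[, , i] * f0
      contrib[f0 == 0] <- 0 # absent class contributes nothing, even if NA
      total[, , i] <- total[, , i] + contrib
    }
  }
  if (renormalize) {
    scale <- ifelse(coverage > 0 & coverage < 1 - tol, 1 / coverage, 1)
    for (i in seq_len(dim(total)[3L])) {
      total[, , i] <- total[, , i] * scale
    }
  }
  for (i in seq_len(dim(total)[3L])) {
    total[, , i][coverage == 0] <- NA_real_
  }
  list(
    composite = monthly_stack(total, s1$spec, s1$years, s1$months,
                              units = "gC m-2 month-1"),
    coverage = raster_grid(coverage, s1$spec, units = "fraction"),
    classes_used = used
  )
}
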