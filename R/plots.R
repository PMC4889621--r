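#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raster_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "Longitude", y = "Latitude",
      fill = if (nzchar(object$units)) object$units else "value"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the grid-mean seasonal course of a monthly stack
#'
#' @param object A [monthly_stack()].
#' @param ... Unused.
#' @return A ggplot of the spatial-mean monthly series.
#' @export
autoplot.monthly_stack <- function(object, ...) {
  df <- tibble::tibble(
    year = object$years,
    month = object$months,
    mean_value = apply(object$values, 3, mean, na.rm = TRUE)
  )
  df$date <- as.Date(sprintf("%04d-%02d-15", df$year, df$month))
  ggplot2::ggplot(df, ggplot2::aes(.data$date, .data$mean_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = NULL,
      y = if (nzchar(object$units)) object$units else "grid mean"
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of an evaluation report
#'
#' Measured (tower-derived) NPP against modelled NPP with the 1:1 line,
#' coloured by season.
#'
#' @param object An `npp_eval_report` from [grouped_reports()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.npp_eval_report <- function(object, ...) {
  ggplot2::ggplot(
    object$pairs,
    ggplot2::aes(.data$npp_model, .data$npp_tower, colour = .data$season)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = expression(Modelled ~ NPP ~ (gC ~ m^-2 ~ month^-1)),
      y = expression(Tower ~ NPP ~ (gC ~ m^-2 ~ month^-1)),
      colour = "Season",
      subtitle = sprintf("Pooled R^2 = %.3f, n = %d",
                         object$pooled$r_squared, object$pooled$n)
    ) +
    ggplot2::theme_minimal()
}
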