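#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_point geom_line
#'   geom_abline labs facet_wrap scale_fill_viridis_c coord_equal theme_minimal
NULL

#' Plot a raster grid
#'
#' @param object a `lichen_grid`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.lichen_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey85") +
    coord_equal() +
    labs(x = "Easting (m)", y = "Northing (m)",
         fill = object$name %||% "value") +
    theme_minimal()
}

#' Plot a reference-area calibration fit
#'
#' @param object a `calibration_model`.
#' @param ... unused.
#' @return A ggplot of target vs source reference means with the fitted
#'   line.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.calibration_model <- function(object, ...) {
  ggplot(object$observations,
         aes(x = .data$source_mean, y = .data$target_mean,
             colour = .data$class)) +
    geom_point(size = 2) +
    geom_abline(slope = object$slope, intercept = object$intercept) +
    labs(x = "Source scene grey level", y = "Target scene grey level",
         colour = "Reference class",
         title = sprintf("y = %.4g x %+.4g   (R² = %.3f, n = %d)",
                         object$slope, object$intercept, object$r_squared,
                         object$n_areas)) +
    theme_minimal()
}

#' Plot the plot-scale lichen regressions
#'
#' @param object a `lichen_regression`.
#' @param ... unused.
#' @return A ggplot with cover and biomass panels against grey level.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.lichen_regression <- function(object, ...) {
  dc <- object$fit_cover$model
  db <- object$fit_biomass$model
  df <- dplyr::bind_rows(
    tibble::tibble(grey = dc$grey, value = dc$cover,
                   response = "2D cover (%)"),
    tibble::tibble(grey = db$grey, value = db$biomass,
                   response = "biomass (g m⁻²)"))
  lines <- tibble::tibble(
    response = c("2D cover (%)", "biomass (g m⁻²)"),
    slope = c(object$cover_slope, object$biomass_slope),
    intercept = c(object$cover_intercept, object$biomass_intercept))
  ggplot(df, aes(x = .data$grey, y = .data$value)) +
    geom_point(alpha = 0.5) +
    geom_abline(data = lines,
                aes(slope = .data$slope, intercept = .data$intercept)) +
    facet_wrap(~response, scales = "free_y") +
    labs(x = "Calibrated grey level", y = NULL) +
    theme_minimal()
}

#' Plot simulated biomass trajectories
#'
#' @param object a `lichen_trajectory` (possibly several variants bound
#'   together).
#' @param ... unused.
#' @return A ggplot of start-of-year biomass by year, one line per
#'   variant.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.lichen_trajectory <- function(object, ...) {
  ggplot(object, aes(x = .data$year, y = .data$b,
                     colour = .data$variant)) +
    geom_line() +
    labs(x = "Year", y = "District lichen biomass (g m⁻²)",
         colour = "Model variant") +
    theme_minimal()
}

#' Plot zonal border-comparison series
#'
#' @param zc a zone-comparison tibble from [zonal_comparison()], typically
#'   stacked over years.
#' @return A ggplot of the side-B/side-A biomass ratio by year and buffer.
#' @export
plot_zone_ratios <- function(zc) {
  ggplot(dplyr::filter(zc, !is.na(.data$year)),
         aes(x = .data$year, y = .data$biomass_ratio,
             colour = factor(.data$buffer_m))) +
    geom_point() + geom_line() +
    labs(x = "Year", y = "Biomass ratio (side B / side A)",
         colour = "Buffer (m)") +
    theme_minimal()
}
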