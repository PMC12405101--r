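#' Convert a multi-band scene to greyscale
#'
#' Per-pixel unweighted mean of the available bands (equal weights for red,
#' green and blue; platforms missing a band are averaged over what they
#' have). Nodata in any band propagates. A single-band scene passes through
#' unchanged.
#'
#' @param scene a `scene` (from [render_scene()]) or a named list of
#'   co-registered `lichen_grid` bands.
#' @return A `lichen_grid` of grey levels.
#' @export
to_greyscale <- function(scene) {
  bands <- if (inherits(scene, "scene")) scene$bands else scene
  if (inherits(bands, "lichen_grid")) return(bands)
  if (!length(bands)) rlang::abort("scene has no bands")
  if (length(bands) == 1) return(bands[[1]])
  g <- bands[[1]]
  for (b in bands[-1]) {
    if (!grid_compatible(g, b)) rlang::abort("bands are not co-registered")
  }
  acc <- Reduce(`+`, purrr::map(bands, "values"))
  g$values <- acc / length(bands)   # NA in any band propagates through +
  g
}

#' Mean greyscale value of each reference area in a scene
#'
#' Averages valid (non-nodata) pixels whose centres fall inside each
#' pseudo-invariant reference polygon. Areas with no valid pixel (e.g.
#' outside the image footprint or under cloud) are kept in the table with
#' `n_pixels = 0` and an `excluded` flag so downstream fits can drop them
#' with a visible reason.
#'
#' @param grey a `lichen_grid` greyscale scene.
#' @param areas tibble of reference areas with `id`, `class` ("dark" or
#'   "bright") and a `polygon` list-column (as produced by
#'   [generate_landscape()]).
#' @return A tibble: `area_id`, `class`, `mean`, `n_pixels`, `excluded`.
#' @export
extract_reference_means <- function(grey, areas) {
  if (!nrow(areas)) rlang::abort("empty reference-area set")
  res <- purrr::map(areas$polygon, ~ polygon_mean(grey, .x))
  tibble::tibble(
    area_id = areas$id,
    class = areas$class,
    mean = purrr::map_dbl(res, "mean"),
    n_pixels = purrr::map_int(res, ~ as.integer(.x$n)),
    excluded = purrr::map_int(res, ~ as.integer(.x$n)) == 0L
  )
}

#' Pair reference-area means from a source and a target scene
#'
#' @param source_means,target_means tibbles from
#'   [extract_reference_means()] for the same polygon set.
#' @return A tibble of reference observations: `area_id`, `class`,
#'   `source_mean`, `target_mean`, `n_pixels_source`, `n_pixels_target`;
#'   areas invalid in either scene are dropped.
#' @export
reference_observations <- function(source_means, target_means) {
  obs <- dplyr::inner_join(
    dplyr::rename(source_means, source_mean = "mean",
                  n_pixels_source = "n_pixels", excl_s = "excluded"),
    dplyr::rename(target_means, target_mean = "mean",
                  n_pixels_target = "n_pixels", excl_t = "excluded"),
    by = c("area_id", "class"))
  dplyr::select(dplyr::filter(obs, !.data$excl_s, !.data$excl_t),
                -"excl_s", -"excl_t")
}

#' Fit a linear radiometric calibration from reference observations
#'
#' Ordinary least squares of the target scene's reference-area means on the
#' source scene's (`target ~ source`), the direction in which the model is
#' applied to source pixels. All valid areas enter unweighted; no outlier
#' rejection.
#'
#' @param observations tibble from [reference_observations()], or any data
#'   frame with `source_mean` and `target_mean` columns.
#' @param source,target optional scene labels stored for provenance.
#' @return A `calibration_model`: slope, intercept, r_squared, n_areas,
#'   the underlying `lm` fit, and labels.
#' @export
fit_calibration <- function(observations, source = NA_character_,
                            target = NA_character_) {
  obs <- dplyr::filter(observations,
                       is.finite(.data$source_mean),
                       is.finite(.data$target_mean))
  if (nrow(obs) < 2) rlang::abort("need >= 2 valid reference observations")
  if (diff(range(obs$source_mean)) < 1e-12) {
    rlang::abort("degenerate calibration: all source means are equal")
  }
  fit <- stats::lm(target_mean ~ source_mean, data = obs)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n_areas = nrow(obs),
    source = source, target = target,
    fit = fit, observations = obs
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> y = %.5g x %+.5g  (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_areas))
  if (!is.na(x$source)) cat(sprintf("  %s -> %s\n", x$source, x$target))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @exportS3Method
tidy.calibration_model <- function(x, ...) {
  tibble::as_tibble(cbind(
    term = c("intercept", "slope"),
    as.data.frame(suppressWarnings(summary(x$fit)$coefficients), row.names = FALSE)
  )) |>
    rlang::set_names(c("term", "estimate", "std_error", "statistic", "p_value"))
}

#' @exportS3Method
glance.calibration_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_areas = x$n_areas,
                 source = x$source, target = x$target)
}

#' Apply a calibration model to a greyscale scene
#'
#' Per-pixel `slope * x + intercept`; nodata preserved. Exactly affine, so
#' calibrating an affinely distorted rendering recovers the target's
#' radiometric scale.
#'
#' @param grey a `lichen_grid`.
#' @param model a `calibration_model`.
#' @return A calibrated `lichen_grid`.
#' @export
apply_calibration <- function(grey, model) {
  stopifnot(inherits(model, "calibration_model"))
  out <- grey
  out$values <- model$slope * grey$values + model$intercept
  out
}

#' Local refinement of a coarsely calibrated high-resolution scene
#'
#' Second step of the two-step very-high-resolution calibration: aggregate
#' the coarsely calibrated mosaic to the target grid, form the difference
#' (aggregated minus target), upsample it block-constant, and subtract.
#' The refined scene then matches the target exactly at the target's scale
#' while keeping all within-cell contrast, removing local colour-balance
#' errors from mosaicking and changing light.
#'
#' @param high_res a `lichen_grid` already coarsely calibrated to the
#'   target's radiometric scale; must be strictly finer than the target
#'   by an integer factor and share its origin.
#' @param target the reference `lichen_grid` (e.g. the anchor satellite
#'   scene), greyscale.
#' @return A refined `lichen_grid` at the high resolution. Cells whose
#'   coarse difference is undefined (target or aggregate nodata) are
#'   passed through unchanged.
#' @export
refine_local <- function(high_res, target) {
  if (high_res$pixel_m >= target$pixel_m) {
    rlang::abort("high_res must be finer than the target scene")
  }
  factor <- target$pixel_m / high_res$pixel_m
  if (abs(factor - round(factor)) > 1e-9) {
    rlang::abort("pixel sizes are not commensurate")
  }
  agg <- grid_aggregate(high_res, round(factor))
  if (!grid_compatible(agg, target)) {
    rlang::abort("scenes do not overlap on a shared grid")
  }
  d <- agg$values - target$values
  if (!any(is.finite(d))) rlang::abort("no overlapping valid cells")
  d[!is.finite(d)] <- 0
  d_hi <- grid_disaggregate(
    lichen_grid(d, agg$xmin, agg$ymin, agg$pixel_m), round(factor))
  out <- high_res
  out$values <- high_res$values - d_hi$values
  out
}
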