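#' Specification of an imaging sensor / platform
#'
#' An idealised single- or multi-band greyscale-capable sensor: ground
#' sampling distance, an affine radiometric distortion (gain, offset)
#' between intrinsic surface reflectance and recorded grey level, additive
#' Gaussian noise, the available visible bands, acquisition year, and the
#' fraction of the domain actually imaged (clouds and partial footprints
#' become nodata). Early satellite platforms lacking a blue channel are
#' emulated with `bands = c("R", "G")`.
#'
#' @param name platform label.
#' @param pixel_m ground sampling distance (m); must be an integer multiple
#'   of the landscape's native pixel.
#' @param gain,offset affine radiometric distortion; `gain` must be nonzero.
#' @param noise_sd additive Gaussian noise sd (grey levels), truncated so
#'   recorded values stay non-negative.
#' @param bands subset of c("R", "G", "B").
#' @param year acquisition year.
#' @param coverage_fraction fraction of the domain imaged, in (0, 1].
#' @return A `sensor_spec` list.
#' @export
sensor_spec <- function(name, pixel_m, gain = 1, offset = 0, noise_sd = 0,
                        bands = c("R", "G", "B"), year = NA_integer_,
                        coverage_fraction = 1) {
  if (pixel_m <= 0) rlang::abort("pixel_m must be positive")
  if (gain == 0) rlang::abort("gain must be nonzero")
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    rlang::abort("coverage_fraction must be in (0, 1]")
  }
  bands <- match.arg(bands, c("R", "G", "B"), several.ok = TRUE)
  structure(list(name = name, pixel_m = pixel_m, gain = gain,
                 offset = offset, noise_sd = noise_sd, bands = bands,
                 year = year, coverage_fraction = coverage_fraction),
            class = "sensor_spec")
}

#' Render a multi-band scene of a landscape through a sensor
#'
#' The inverse of the calibration problem: intrinsic reflectance is
#' aggregated to the sensor grid (unweighted mean of native cells whose
#' centres fall in each coarse pixel), then distorted per band as
#' `gain * reflectance + offset + noise`. All bands see the same surface
#' reflectance (the landscape is spectrally grey); band-to-band differences
#' come only from independent noise draws. Cells outside the imaged
#' footprint are nodata.
#'
#' @param landscape a `true_landscape`.
#' @param sensor a [sensor_spec()].
#' @param seed integer seed for the noise and footprint placement; defaults
#'   to a stream derived from the landscape seed and the sensor identity.
#' @return A `scene`: list of per-band `lichen_grid`s plus the sensor spec.
#' @export
render_scene <- function(landscape, sensor,
                         seed = seed_from(landscape$spec$seed, sensor$name,
                                          sensor$year)) {
  stopifnot(inherits(landscape, "true_landscape"),
            inherits(sensor, "sensor_spec"))
  base_px <- landscape$spec$base_pixel_m
  if (sensor$pixel_m < base_px) {
    rlang::abort("sensor pixel_m must be >= the landscape base pixel")
  }
  factor <- sensor$pixel_m / base_px
  if (abs(factor - round(factor)) > 1e-9) {
    rlang::abort("sensor pixel_m must be an integer multiple of the base pixel")
  }
  refl <- grid_aggregate(landscape$reflectance, round(factor))
  with_seed(seed, {
    mask <- matrix(FALSE, nrow(refl$values), ncol(refl$values))
    if (sensor$coverage_fraction < 1) {
      # random axis-aligned sub-window with the requested area fraction
      fr <- sqrt(sensor$coverage_fraction)
      nr <- nrow(mask); nc <- ncol(mask)
      wr <- max(1L, round(fr * nr)); wc <- max(1L, round(fr * nc))
      r0 <- sample.int(nr - wr + 1L, 1); c0 <- sample.int(nc - wc + 1L, 1)
      mask[r0:(r0 + wr - 1L), c0:(c0 + wc - 1L)] <- TRUE
      mask <- !mask
    }
    bands <- purrr::map(rlang::set_names(sensor$bands), function(b) {
      v <- sensor$gain * refl$values + sensor$offset
      if (sensor$noise_sd > 0) {
        v <- v + stats::rnorm(length(v), 0, sensor$noise_sd)
        v <- pmax(v, 0)
      }
      v[mask] <- NA_real_
      lichen_grid(v, refl$xmin, refl$ymin, refl$pixel_m,
                  year = sensor$year, name = sensor$name)
    })
    structure(list(bands = bands, sensor = sensor), class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %s (%s), %g m pixels, bands: %s\n",
              x$sensor$name,
              ifelse(is.na(x$sensor$year), "year ?", x$sensor$year),
              x$sensor$pixel_m, paste(names(x$bands), collapse = ",")))
  invisible(x)
}
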