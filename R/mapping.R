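#' Forage-lichen volume from cover and mat thickness
#'
#' The plot formula `v = c h` with cover as a fraction: a 1-mm mat over
#' 1 m^2 is 1 dm^3, so volume in dm^3 m^-2 is `(cover3d_pct / 100) *
#' height_mm`. Cover is the summed 3D cover of layered forage-lichen
#' species (may exceed 100).
#'
#' @param cover3d_pct 3D cover percentage (>= 0).
#' @param height_mm mean lichen mat thickness in mm (>= 0).
#' @return Volume in dm^3 per m^2.
#' @export
plot_volume <- function(cover3d_pct, height_mm) {
  if (any(cover3d_pct < 0, na.rm = TRUE) || any(height_mm < 0, na.rm = TRUE)) {
    rlang::abort("cover and height must be non-negative")
  }
  (cover3d_pct / 100) * height_mm
}

#' Forage-lichen dry biomass from volume
#'
#' `b = 22 v`: one dm^3 of reindeer lichen weighs 22 g dry.
#'
#' @param volume_dm3_m2 lichen volume (dm^3 m^-2, >= 0).
#' @return Dry biomass in g m^-2.
#' @export
plot_biomass <- function(volume_dm3_m2) {
  if (any(volume_dm3_m2 < 0, na.rm = TRUE)) {
    rlang::abort("volume must be non-negative")
  }
  22 * volume_dm3_m2
}

#' Point-intercept 2D cover from a plot photograph mask
#'
#' Overlays a regular square grid of crosshairs on a binary lichen mask and
#' scores the fraction of hits: 50 hits out of 100 crosshairs is 50\% cover.
#' Crosshairs sit at the centres of a sqrt(n) x sqrt(n) grid of equal cells.
#'
#' @param mask binary matrix (1 = forage lichen).
#' @param grid_n number of crosshairs; must be a perfect square.
#' @return 2D cover percentage.
#' @export
point_intercept_cover <- function(mask, grid_n = 100) {
  if (!length(mask)) rlang::abort("empty mask image")
  k <- sqrt(grid_n)
  if (k != round(k)) rlang::abort("grid_n must be a perfect square")
  u <- (seq_len(k) - 0.5) / k
  rows <- ceiling(u * nrow(mask))
  cols <- ceiling(u * ncol(mask))
  hits <- sum(mask[rows, cols] != 0)
  100 * hits / grid_n
}

#' Fit the greyscale-to-cover and greyscale-to-biomass regressions
#'
#' Two independent OLS fits on the training plots: 2D cover (\%) on mean
#' grey level, and dry biomass (g m^-2) on mean grey level. Derives the
#' zero-crossing grey value (below which predicted cover is negative and
#' maps are clamped to zero) and the biomass cap (the biomass prediction
#' at the grey value where predicted cover reaches 100\%).
#'
#' @param plots data frame with `cover2d_pct`, `biomass_g_m2`, and a grey
#'   column.
#' @param grey_col name of the grey-level column (default "grey_mean").
#' @return A `lichen_regression`: cover and biomass slopes/intercepts,
#'   `zero_cross_grey`, `cap_biomass_g_m2`, R^2 values, and the `lm` fits.
#' @export
fit_plot_regressions <- function(plots, grey_col = "grey_mean") {
  df <- tibble::tibble(
    grey = plots[[grey_col]],
    cover = plots$cover2d_pct,
    biomass = plots$biomass_g_m2
  )
  df <- dplyr::filter(df, stats::complete.cases(df))
  if (nrow(df) < 3) rlang::abort("need >= 3 complete plots")
  if (diff(range(df$grey)) < 1e-12) {
    rlang::abort("degenerate design: all grey values equal")
  }
  fc <- stats::lm(cover ~ grey, data = df)
  fb <- stats::lm(biomass ~ grey, data = df)
  cs <- unname(stats::coef(fc)); bs <- unname(stats::coef(fb))
  if (cs[2] <= 0) {
    rlang::warn("cover regression slope is not positive; lichen should brighten the image")
  }
  grey100 <- (100 - cs[1]) / cs[2]
  structure(list(
    cover_slope = cs[2], cover_intercept = cs[1],
    biomass_slope = bs[2], biomass_intercept = bs[1],
    zero_cross_grey = -cs[1] / cs[2],
    grey_at_full_cover = grey100,
    cap_biomass_g_m2 = max(0, bs[1] + bs[2] * grey100),
    r2_cover = suppressWarnings(summary(fc)$r.squared),
    r2_biomass = suppressWarnings(summary(fb)$r.squared),
    n_plots = nrow(df),
    fit_cover = fc, fit_biomass = fb
  ), class = "lichen_regression")
}

#' @export
print.lichen_regression <- function(x, ...) {
  cat(sprintf(
    paste0("<lichen_regression> n = %d plots\n",
           "  cover   = %.4g * grey %+.4g   (R^2 = %.2f)\n",
           "  biomass = %.4g * grey %+.4g   (R^2 = %.2f)\n",
           "  zero-cover grey %.4g; biomass cap %.0f g m^-2 at 100%% cover\n"),
    x$n_plots, x$cover_slope, x$cover_intercept, x$r2_cover,
    x$biomass_slope, x$biomass_intercept, x$r2_biomass,
    x$zero_cross_grey, x$cap_biomass_g_m2))
  invisible(x)
}

#' @exportS3Method
tidy.lichen_regression <- function(x, ...) {
  one <- function(fit, response) {
    co <- suppressWarnings(summary(fit)$coefficients)
    tibble::tibble(response = response,
                   term = c("intercept", "slope"),
                   estimate = co[, 1], std_error = co[, 2],
                   statistic = co[, 3], p_value = co[, 4])
  }
  dplyr::bind_rows(one(x$fit_cover, "cover2d_pct"),
                   one(x$fit_biomass, "biomass_g_m2"))
}

#' @exportS3Method
glance.lichen_regression <- function(x, ...) {
  tibble::tibble(r2_cover = x$r2_cover, r2_biomass = x$r2_biomass,
                 zero_cross_grey = x$zero_cross_grey,
                 cap_biomass_g_m2 = x$cap_biomass_g_m2, n_plots = x$n_plots)
}

#' Mean grey level around each plot centre
#'
#' Averages scene pixels whose centres fall within a disc of the given
#' radius around each plot centre (the plot-to-image link). When the scene
#' pixel is coarser than the disc, the value of the pixel containing the
#' plot centre is used.
#'
#' @param grey a `lichen_grid` (normally the calibrated high-resolution
#'   mosaic).
#' @param plots plot tibble with `x`, `y`.
#' @param radius_m disc radius in metres (default 0.35 m, approximately a
#'   0.4 m^2 footprint on a 0.25 m^2 plot).
#' @return `plots` with a `grey_mean` column added.
#' @export
extract_plot_grey <- function(grey, plots, radius_m = 0.35) {
  vals <- purrr::map2_dbl(plots$x, plots$y, function(x, y) {
    if (radius_m >= grey$pixel_m / 2) {
      pm <- polygon_mean(grey, disc_polygon(x, y, radius_m))
      if (pm$n > 0) return(pm$mean)
    }
    grid_value_at(grey, x, y)
  })
  dplyr::mutate(plots, grey_mean = vals)
}

#' Predict cover and biomass maps from a calibrated scene
#'
#' Applies the plot-trained regressions pixelwise, then enforces the
#' physical range: negative predicted cover is reclassified as zero, cover
#' is capped at 100\%, and biomass is clamped to [0, cap] where the cap is
#' the biomass prediction at the grey value of 100\% cover. Pixels whose
#' cover prediction is zero get zero biomass. Excluded land-cover classes
#' (default: forest, water, mire, sand) become nodata and are recorded in
#' an exclusion mask.
#'
#' @param grey a calibrated `lichen_grid`.
#' @param reg a `lichen_regression`.
#' @param landcover optional co-registered land-cover `lichen_grid`; when
#'   missing, maps are produced with an empty mask and a warning.
#' @param exclude character vector of class names to mask out.
#' @return A `lichen_map_pair`: grids `cover` (\%), `biomass` (g m^-2,
#'   equal to t km^-2), `excluded_mask` (logical), plus `year` and the
#'   regression used.
#' @export
predict_maps <- function(grey, reg, landcover = NULL,
                         exclude = c("forest", "water", "mire", "sand")) {
  stopifnot(inherits(reg, "lichen_regression"))
  cover_v <- reg$cover_intercept + reg$cover_slope * grey$values
  cover_v <- pmin(100, pmax(0, cover_v))
  bio_v <- reg$biomass_intercept + reg$biomass_slope * grey$values
  bio_v <- pmin(reg$cap_biomass_g_m2, pmax(0, bio_v))
  bio_v[!is.na(cover_v) & cover_v == 0] <- 0
  dim(cover_v) <- dim(grey$values)
  dim(bio_v) <- dim(grey$values)
  excl <- matrix(FALSE, nrow(grey$values), ncol(grey$values))
  if (is.null(landcover)) {
    rlang::warn("no land-cover grid supplied: no classes excluded from the maps")
  } else {
    lc <- landcover
    if (lc$pixel_m != grey$pixel_m) {
      f <- grey$pixel_m / lc$pixel_m
      if (abs(f - round(f)) > 1e-9 || f < 1) {
        rlang::abort("land cover is not commensurate with the scene grid")
      }
      # majority-free downsample: a coarse cell is excluded when the
      # excluded classes cover more than half of it
      codes <- landcover_code(exclude)
      excl_fine <- lichen_grid(
        matrix((lc$values %in% codes) + 0, nrow(lc$values), ncol(lc$values)),
        lc$xmin, lc$ymin, lc$pixel_m)
      excl <- grid_aggregate(excl_fine, round(f))$values > 0.5
    } else {
      excl <- matrix(lc$values %in% landcover_code(exclude),
                     nrow(lc$values), ncol(lc$values))
    }
    cover_v[excl] <- NA_real_
    bio_v[excl] <- NA_real_
  }
  structure(list(
    cover = lichen_grid(cover_v, grey$xmin, grey$ymin, grey$pixel_m,
                        grey$year, grey$name),
    biomass = lichen_grid(bio_v, grey$xmin, grey$ymin, grey$pixel_m,
                          grey$year, grey$name),
    excluded_mask = lichen_grid(excl + 0, grey$xmin, grey$ymin, grey$pixel_m),
    year = grey$year,
    regression = reg
  ), class = "lichen_map_pair")
}

#' Zonal comparison of lichen cover and biomass across a border
#'
#' For each buffer distance, averages valid map cells whose centres lie
#' within the Euclidean buffer of the border polyline, separately per side,
#' and reports the side-B / side-A ratios (B is the Norway-analogue east
#' side in synthetic landscapes). Cells excluded by the map's land-cover
#' mask are already nodata and drop out.
#'
#' @param map_pair a `lichen_map_pair`.
#' @param border_line two-column polyline matrix.
#' @param buffers_m buffer distances in metres (default 200 m and 10 km).
#' @return A tibble with one row per buffer: means, cell counts, ratios,
#'   and an `undefined` flag when a side has no valid cell or a zero mean.
#' @export
zonal_comparison <- function(map_pair, border_line,
                             buffers_m = c(200, 10000)) {
  g <- map_pair$cover
  cc <- grid_coords(g)
  px <- rep(cc$x, each = length(cc$y))
  py <- rep(cc$y, times = length(cc$x))
  pd <- polyline_distance(px, py, border_line)
  if (min(pd$dist) > max(buffers_m)) {
    rlang::abort("border line does not intersect the map extent")
  }
  cov <- as.vector(map_pair$cover$values)
  bio <- as.vector(map_pair$biomass$values)
  purrr::map_dfr(buffers_m, function(buf) {
    inz <- pd$dist <= buf & !is.na(cov)
    a <- inz & pd$side == "A"; b <- inz & pd$side == "B"
    mca <- if (any(a)) mean(cov[a]) else NA_real_
    mcb <- if (any(b)) mean(cov[b]) else NA_real_
    mba <- if (any(a)) mean(bio[a]) else NA_real_
    mbb <- if (any(b)) mean(bio[b]) else NA_real_
    tibble::tibble(
      year = map_pair$year, buffer_m = buf,
      mean_cover_A = mca, mean_cover_B = mcb,
      mean_biomass_A = mba, mean_biomass_B = mbb,
      n_cells_A = sum(a), n_cells_B = sum(b),
      cover_ratio = ifelse(is.na(mca) || mca <= 0, NA_real_, mcb / mca),
      biomass_ratio = ifelse(is.na(mba) || mba <= 0, NA_real_, mbb / mba),
      undefined = !any(a) || !any(b) ||
        isTRUE(mca <= 0) || isTRUE(mba <= 0)
    )
  })
}

#' District-mean lichen biomass
#'
#' Mean predicted biomass over valid cells inside a district polygon.
#' Forest, water and bare sand are always excluded; mires are included by
#' default (the
#' whole-district modelling convention) or excluded for comparisons with
#' surveys that skip bogs. One g m^-2 equals one tonne km^-2.
#'
#' @param map_pair a `lichen_map_pair` built WITHOUT masking the classes
#'   this function controls, or any map pair — cells already nodata stay
#'   excluded.
#' @param polygon district polygon (two-column matrix).
#' @param landcover co-registered land-cover `lichen_grid` (native or map
#'   resolution).
#' @param include_mires include mire cells in the mean (default TRUE).
#' @return A tibble: `year`, `mean_biomass_t_km2`, `mean_cover_pct`,
#'   `n_cells`, `include_mires`.
#' @export
district_mean <- function(map_pair, polygon, landcover = NULL,
                          include_mires = TRUE) {
  inside <- cells_in_polygon(map_pair$biomass, polygon)
  if (!any(inside)) rlang::abort("district polygon contains no map cells")
  keep <- inside & !is.na(map_pair$biomass$values)
  if (!is.null(landcover)) {
    lc <- landcover
    hard <- landcover_code(c("forest", "water", "sand"))
    if (lc$pixel_m != map_pair$biomass$pixel_m) {
      f <- map_pair$biomass$pixel_m / lc$pixel_m
      lcv <- grid_aggregate(
        lichen_grid(matrix((lc$values %in% hard) + 0,
                           nrow(lc$values), ncol(lc$values)),
                    lc$xmin, lc$ymin, lc$pixel_m), round(f))$values > 0.5
      mire <- grid_aggregate(
        lichen_grid(matrix((lc$values == landcover_code("mire")) + 0,
                           nrow(lc$values), ncol(lc$values)),
                    lc$xmin, lc$ymin, lc$pixel_m), round(f))$values > 0.5
    } else {
      lcv <- matrix(lc$values %in% hard, nrow(lc$values))
      mire <- matrix(lc$values == landcover_code("mire"), nrow(lc$values))
    }
    keep <- keep & !lcv
    if (!include_mires) keep <- keep & !mire
  }
  if (!any(keep)) rlang::abort("no valid cells in district polygon")
  tibble::tibble(
    year = map_pair$year,
    mean_biomass_t_km2 = mean(map_pair$biomass$values[keep]),
    mean_cover_pct = mean(map_pair$cover$values[keep], na.rm = TRUE),
    n_cells = sum(keep),
    include_mires = include_mires
  )
}

#' Resolution-rescaling coefficients of mapped biomass
#'
#' Aggregates the greyscale scene to coarser pixel sizes (unweighted mean),
#' re-applies the lichen regressions at each resolution, and reports mean
#' mapped biomass relative to the native resolution. Because bright patches
#' are averaged below the cover zero-crossing before clamping, coefficients
#' on patchy landscapes fall below 1 and decrease with pixel size.
#'
#' @param grey calibrated `lichen_grid` at native resolution.
#' @param reg a `lichen_regression`.
#' @param pixel_sizes_m target pixel sizes (m); each must be an integer
#'   multiple of the native pixel.
#' @param landcover,exclude passed to [predict_maps()] (land cover is used
#'   at native resolution and aggregated alongside).
#' @return A tibble: `pixel_m`, `mean_biomass_t_km2`, `coefficient`
#'   (biomass at that resolution / biomass at native; 1.00 for native).
#' @export
rescale_coefficients <- function(grey, reg, pixel_sizes_m = c(10, 30, 60),
                                 landcover = NULL,
                                 exclude = c("forest", "water", "mire", "sand")) {
  sizes <- sort(unique(c(grey$pixel_m, pixel_sizes_m)))
  rows <- list()
  for (pxm in sizes) {
    f <- pxm / grey$pixel_m
    if (abs(f - round(f)) > 1e-9 ||
        nrow(grey$values) %% round(f) != 0 ||
        ncol(grey$values) %% round(f) != 0) {
      rlang::abort(sprintf("pixel size %g m is not a multiple of native %g m",
                           pxm, grey$pixel_m))
    }
    gg <- if (round(f) == 1) grey else grid_aggregate(grey, round(f))
    mp <- suppressWarnings(predict_maps(gg, reg, landcover, exclude))
    rows[[length(rows) + 1]] <- tibble::tibble(
      pixel_m = pxm,
      mean_biomass_t_km2 = mean(mp$biomass$values, na.rm = TRUE))
  }
  dplyr::mutate(dplyr::bind_rows(rows),
    coefficient = .data$mean_biomass_t_km2 / .data$mean_biomass_t_km2[1])
}

#' Weighted mean absolute percent error
#'
#' `wMAPE = sum(|O - S|) / sum(|O|)`: absolute reconstruction errors summed
#' over the validation pairs, weighted by the observed magnitudes.
#'
#' @param pairs data frame with observed and reconstructed columns.
#' @param observed,reconstructed column names.
#' @return The wMAPE as a fraction (multiply by 100 for percent).
#' @export
wmape <- function(pairs, observed = "observed", reconstructed = "reconstructed") {
  o <- pairs[[observed]]; s <- pairs[[reconstructed]]
  if (sum(abs(o)) <= 0) rlang::abort("all observed values are zero")
  sum(abs(o - s)) / sum(abs(o))
}
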