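#' Truth value at a point (containing cell)
#'
#' @param g a `lichen_grid`.
#' @param x,y planar coordinates (m).
#' @return numeric vector of cell values (NA outside the grid).
#' @export
grid_value_at <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  col <- floor((x - g$xmin) / g$pixel_m) + 1
  row <- nr - floor((y - g$ymin) / g$pixel_m)
  ok <- col >= 1 & col <= nc & row >= 1 & row <= nr
  out <- rep(NA_real_, length(x))
  out[ok] <- g$values[cbind(row[ok], col[ok])]
  out
}

#' Simulate a point-intercept vegetation-plot campaign
#'
#' Lays transects perpendicular to the border fence, half of each transect
#' on either side, with plots at a fixed interval (defaults: five 400-m
#' transects of forty 0.25-m^2 plots at 10-m spacing). Transect northings
#' are chosen preferentially where the line crosses open heath, as field
#' crews site campaigns on treeless tundra; each plot also records the
#' land-cover class under its centre. Each plot records
#' the field-style measurements: summed 3D forage-lichen cover (layered
#' species, may exceed the 2D cover), mean lichen mat thickness (mm), the
#' true vertically-projected 2D cover (\%), plot-formula volume and biomass,
#' and a binary overhead photograph mask whose lichen-pixel fraction matches
#' the 2D cover to within 1\%. The 3D/2D gap and the height reading vary
#' plot-to-plot, which is what makes field biomass noisier than cover when
#' regressed on image grey levels.
#'
#' @param landscape a `true_landscape`.
#' @param n_transects number of transects.
#' @param plots_per_transect plots per transect (even; half per side).
#' @param spacing_m along-transect plot interval (m).
#' @param site site label attached to every plot.
#' @param y_range optional c(min, max) northing band for the transects.
#' @param mask_dim side length of the binary plot photograph (pixels).
#' @param seed integer seed (default derived from the landscape seed).
#' @return A tibble with one row per plot: `plot_id`, `site`, `transect`,
#'   `side`, `x`, `y`, `cover2d_pct`, `cover3d_pct`, `height_mm`,
#'   `volume_dm3_m2`, `biomass_g_m2`, and a `mask` list-column of binary
#'   matrices.
#' @export
generate_plots <- function(landscape, n_transects = 5,
                           plots_per_transect = 40, spacing_m = 10,
                           site = "site1", y_range = NULL, mask_dim = 50,
                           seed = seed_from(landscape$spec$seed, "plots", site)) {
  stopifnot(inherits(landscape, "true_landscape"))
  spec <- landscape$spec
  half <- plots_per_transect / 2 * spacing_m
  if (spec$border_x - half < 0 || spec$border_x + half > spec$extent_m[1]) {
    rlang::abort("transects do not fit inside the domain on both sides of the border")
  }
  if (is.null(y_range)) y_range <- c(0.05, 0.95) * spec$extent_m[2]
  with_seed(seed, {
    # field crews lay transects on open tundra heath: among candidate
    # northings, keep those whose plot line crosses the most heath
    cand <- seq(y_range[1], y_range[2], length.out = max(40, 8 * n_transects))
    offs <- (seq_len(plots_per_transect) - (plots_per_transect + 1) / 2) * spacing_m
    heath_frac <- vapply(cand, function(yy) {
      lc <- grid_value_at(landscape$landcover, spec$border_x + offs,
                          rep(yy, length(offs)))
      mean(lc == landcover_code("heath"), na.rm = TRUE)
    }, numeric(1))
    keep <- order(-heath_frac)
    min_sep <- min(50, diff(y_range) / (1.5 * n_transects))
    ty <- numeric(0)
    for (i in keep) {   # greedy pick, transects kept apart
      if (all(abs(cand[i] - ty) >= min_sep)) ty <- c(ty, cand[i])
      if (length(ty) == n_transects) break
    }
    if (length(ty) < n_transects) {
      rlang::abort("domain too small to place the requested transects")
    }
    ty <- sort(ty)
    grid <- tidyr::expand_grid(transect = seq_len(n_transects),
                               off = offs)
    grid <- dplyr::mutate(grid,
      x = spec$border_x + .data$off,
      y = ty[.data$transect],
      side = ifelse(.data$off < 0, "A", "B"))

    cover2d <- grid_value_at(landscape$cover, grid$x, grid$y)
    h_true <- grid_value_at(landscape$height, grid$x, grid$y)
    # layered species inflate the summed 3D cover; the mean mat thickness
    # measured at lichen points shrinks correspondingly, so the plot
    # volume formula stays an unbiased (if noisy) estimate of the true
    # lichen volume, with the extra height noise making field biomass a
    # noisier signal than 2D cover
    layer <- stats::runif(nrow(grid), 1.05, 1.45)
    h_meas <- h_true / layer * stats::runif(nrow(grid), 0.85, 1.15)
    cover3d <- ifelse(cover2d > 0, cover2d * layer, 0)
    h_meas[cover3d == 0] <- 0
    volume <- plot_volume(cover3d, h_meas)
    masks <- purrr::map(cover2d, function(cv) {
      m <- matrix(0L, mask_dim, mask_dim)
      k <- round(cv / 100 * mask_dim^2)
      if (k > 0) m[sample.int(mask_dim^2, k)] <- 1L
      m
    })
    tibble::tibble(
      plot_id = sprintf("%s-t%d-p%03d", site, grid$transect,
                        rep(seq_len(plots_per_transect), times = n_transects)),
      site = site,
      transect = grid$transect,
      side = grid$side,
      x = grid$x, y = grid$y,
      cover2d_pct = cover2d,
      cover3d_pct = cover3d,
      height_mm = h_meas,
      volume_dm3_m2 = volume,
      biomass_g_m2 = plot_biomass(volume),
      landcover = names(LANDCOVER_LEVELS)[
        grid_value_at(landscape$landcover, grid$x, grid$y)],
      mask = masks
    )
  })
}

#' Generate an annual reindeer census series
#'
#' A deterministic trend (exponential growth from a base herd size) with
#' optional year-specific shock multipliers (emulating herd crashes after
#' harsh winters) and multiplicative noise. Counts are annual averages and
#' may be fractional.
#'
#' @param years integer vector of census years.
#' @param base_count herd size in the first year (animals).
#' @param area_km2 district area.
#' @param occupancy_days days per year the counted population spends in the
#'   district (365 = year-round use; a winter district is much less).
#' @param growth_rate annual proportional trend growth.
#' @param shocks optional named numeric, e.g. `c("1997" = 0.7)`: multiplier
#'   applied to that year's trend value.
#' @param noise_cv coefficient of variation of multiplicative noise.
#' @param seed integer seed.
#' @return A tibble: `year`, `count`, `area_km2`, `occupancy_days`.
#' @export
generate_census <- function(years, base_count, area_km2,
                            occupancy_days = 365, growth_rate = 0,
                            shocks = NULL, noise_cv = 0, seed = 1L) {
  if (!length(years)) rlang::abort("years must be non-empty")
  with_seed(seed, {
    trend <- base_count * (1 + growth_rate)^(years - years[1])
    mult <- rep(1, length(years))
    if (!is.null(shocks)) {
      idx <- match(as.integer(names(shocks)), years)
      mult[idx[!is.na(idx)]] <- shocks[!is.na(idx)]
    }
    count <- trend * mult
    if (noise_cv > 0) {
      count <- count * pmax(0, 1 + stats::rnorm(length(years), 0, noise_cv))
    }
    tibble::tibble(year = as.integer(years), count = pmax(0, count),
                   area_km2 = area_km2, occupancy_days = occupancy_days)
  })
}

#' Reindeer-year densities from a census table
#'
#' Applies [reindeer_year_density()] row-wise: density in reindeer-years
#' per km^2 is the animal density scaled by the fraction of the year the
#' population occupies the district.
#'
#' @param census tibble from [generate_census()] (or with the same columns).
#' @return A tibble: `year`, `d` (reindeer-years km^-2).
#' @export
census_to_density <- function(census) {
  tibble::tibble(
    year = census$year,
    d = reindeer_year_density(census$count, census$area_km2,
                              census$occupancy_days)
  )
}

#' Forward-simulate a noisy "reconstructed" biomass series
#'
#' Ground truth for the loss-parameter recovery studies: runs the district
#' biomass model forward and observes it at the mapped years only, with
#' i.i.d. multiplicative observation noise (truncated at zero), emulating a
#' remote-sensing reconstruction of known error.
#'
#' @param params a [model_params()].
#' @param densities tibble `year`, `d`.
#' @param fts tibble `year`, `f` (landscape growth factors).
#' @param b0 initial biomass (g m^-2).
#' @param noise_sd multiplicative observation noise sd (fraction; 0.1 = 10\%).
#' @param sample_years years at which the series is observed; must lie
#'   within the simulated range.
#' @param seed integer seed.
#' @return A tibble: `year`, `biomass` (g m^-2).
#' @export
forward_reconstruction_series <- function(params, densities, fts, b0,
                                          noise_sd = 0, sample_years,
                                          seed = 1L) {
  sim <- simulate_biomass(b0, densities$year, densities, fts, params)
  missing <- setdiff(sample_years, sim$year)
  if (length(missing)) {
    rlang::abort(sprintf("sample_years outside simulation range: %s",
                         paste(missing, collapse = ", ")))
  }
  b <- sim$b[match(sample_years, sim$year)]
  with_seed(seed, {
    if (noise_sd > 0) b <- pmax(0, b * (1 + stats::rnorm(length(b), 0, noise_sd)))
    tibble::tibble(year = as.integer(sample_years), biomass = b)
  })
}
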