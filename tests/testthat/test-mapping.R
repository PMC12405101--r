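test_that("plot volume and biomass formulas match their worked examples", {
  expect_equal(plot_volume(100, 50), 50)
  expect_equal(plot_volume(0, 123), 0)
  expect_equal(plot_volume(40, 25), 10)
  expect_error(plot_volume(-1, 10), "non-negative")
  expect_equal(plot_biomass(1), 22)
  expect_equal(plot_biomass(0), 0)
  # 10 m^3 of lichen over a square metre = 10,000 dm^3 -> 220 kg dry
  expect_equal(plot_biomass(10000), 220000)
})

test_that("plot regressions recover an exact linear law and its anchors", {
  grey <- seq(400, 900, length.out = 12)
  plots <- tibble::tibble(
    grey_mean = grey,
    cover2d_pct = 0.2 * grey - 82,       # zero-crossing at grey 410
    biomass_g_m2 = 4 * grey - 1500
  )
  reg <- fit_plot_regressions(plots)
  expect_equal(reg$cover_slope, 0.2, tolerance = 1e-9)
  expect_equal(reg$cover_intercept, -82, tolerance = 1e-6)
  expect_equal(reg$r2_cover, 1)
  expect_equal(reg$zero_cross_grey, 410, tolerance = 1e-6)
  # zero-crossing agrees with a root-finding oracle on the fitted line
  root <- uniroot(function(g) reg$cover_intercept + reg$cover_slope * g,
                  c(0, 2000))$root
  expect_equal(reg$zero_cross_grey, root, tolerance = 1e-6)
  # cap = biomass prediction at the grey level of 100% cover
  grey100 <- (100 - reg$cover_intercept) / reg$cover_slope
  expect_equal(reg$cap_biomass_g_m2, 4 * grey100 - 1500, tolerance = 1e-6)
  expect_error(fit_plot_regressions(plots[1:2, ]), ">= 3")
  expect_error(fit_plot_regressions(
    dplyr::mutate(plots, grey_mean = 5)), "degenerate")
})

test_that("field biomass is a noisier function of grey than 2D cover", {
  land <- test_landscape()
  g <- to_greyscale(render_scene(land, ideal_sensor()))
  plots <- extract_plot_grey(g, generate_plots(land))
  plots <- dplyr::filter(plots, .data$landcover == "heath")
  reg <- fit_plot_regressions(plots)
  expect_gt(reg$r2_cover, reg$r2_biomass)
  expect_gt(reg$r2_cover, 0.9)   # noiseless sensor: cover is almost exact
})

test_that("map predictions are clamped, consistent and class-masked", {
  grey <- matrix(c(100, 410, 500, 910, 2000, NA), 2, 3)
  reg <- fit_plot_regressions(tibble::tibble(
    grey_mean = seq(400, 900, length.out = 6),
    cover2d_pct = 0.2 * seq(400, 900, length.out = 6) - 82,
    biomass_g_m2 = 4 * seq(400, 900, length.out = 6) - 1500))
  g <- lichen_grid(grey, pixel_m = 10)
  lc <- lichen_grid(matrix(landcover_code("heath"), 2, 3), pixel_m = 10)
  lc$values[2, 3] <- landcover_code("water")
  mp <- predict_maps(g, reg, lc)
  # below the zero-crossing: cover and biomass both reclassified to zero
  expect_equal(mp$cover$values[1, 1], 0)
  expect_equal(mp$biomass$values[1, 1], 0)
  # at 100% cover grey (910): biomass equals the cap exactly
  expect_equal(mp$cover$values[2, 2], 100)
  expect_equal(mp$biomass$values[2, 2], reg$cap_biomass_g_m2)
  # beyond: clamped
  expect_equal(mp$cover$values[1, 3], 100)
  expect_equal(mp$biomass$values[1, 3], reg$cap_biomass_g_m2)
  # excluded water cell is nodata in both maps and flagged
  expect_true(is.na(mp$cover$values[2, 3]))
  expect_true(is.na(mp$biomass$values[2, 3]))
  expect_equal(mp$excluded_mask$values[2, 3], 1)
  # no land cover: warns, produces empty mask
  expect_warning(mp2 <- predict_maps(g, reg), "land-cover")
  expect_true(all(mp2$excluded_mask$values == 0))
})

test_that("predicted maps never leave the physical ranges and rise with grey", {
  land <- test_landscape()
  g <- to_greyscale(render_scene(land,
    sensor_spec("noisy", 10, gain = 1.3, offset = 12, noise_sd = 4,
                year = 2000L)))
  plots <- extract_plot_grey(to_greyscale(render_scene(land, ideal_sensor())),
                             generate_plots(land))
  reg <- fit_plot_regressions(dplyr::filter(plots, .data$landcover == "heath"))
  mp <- suppressWarnings(predict_maps(g, reg))
  cv <- mp$cover$values[!is.na(mp$cover$values)]
  bv <- mp$biomass$values[!is.na(mp$biomass$values)]
  expect_true(all(cv >= 0 & cv <= 100))
  expect_true(all(bv >= 0 & bv <= reg$cap_biomass_g_m2))
  # monotone in grey between the zero-cross and full-cover grey levels
  gs <- seq(reg$zero_cross_grey, reg$grey_at_full_cover, length.out = 50)
  gg <- lichen_grid(matrix(gs, 1), pixel_m = 10)
  mp2 <- suppressWarnings(predict_maps(gg, reg))
  expect_true(all(diff(mp2$cover$values[1, ]) >= -1e-12))
  expect_true(all(diff(mp2$biomass$values[1, ]) >= -1e-12))
})

test_that("zonal comparison reproduces constructed side means and ratios", {
  # 40 x 40 cells of 10 m; border at x = 200
  cov <- matrix(0, 40, 40)
  cov[, 1:20] <- 28; cov[, 21:40] <- 42
  bio <- cov * 10
  mp <- make_map_pair(cov, bio)
  border <- rbind(c(200, 400), c(200, 0))
  zc <- zonal_comparison(mp, border, buffers_m = c(50, 10000))
  wide <- zc[zc$buffer_m == 10000, ]
  expect_equal(wide$mean_cover_A, 28)
  expect_equal(wide$mean_cover_B, 42)
  expect_equal(wide$cover_ratio, 1.5)
  expect_equal(wide$biomass_ratio, 1.5)
  # zonal-mean oracle: direct masked mean over the wide buffer
  cc <- grid_coords(mp$cover)
  xmat <- matrix(rep(cc$x, each = 40), 40, 40)
  expect_equal(wide$mean_cover_A,
               mean(cov[abs(xmat - 200) <= 10000 & xmat < 200]))
  # narrow buffer cells are a subset of the wide buffer cells
  narrow <- zc[zc$buffer_m == 50, ]
  expect_lte(narrow$n_cells_A + narrow$n_cells_B,
             wide$n_cells_A + wide$n_cells_B)
  # symmetric map: ratios are exactly 1
  sym <- make_map_pair(matrix(33, 40, 40), matrix(330, 40, 40))
  zs <- zonal_comparison(sym, border, buffers_m = c(50, 10000))
  expect_true(all(zs$cover_ratio == 1))
  expect_true(all(zs$biomass_ratio == 1))
})

test_that("district means respect units, masks and the mire flag", {
  cov <- matrix(50, 20, 20)
  bio <- matrix(100, 20, 20)
  mp <- make_map_pair(cov, bio)
  poly <- rect_polygon(0, 200, 0, 200)
  # constant 100 g m^-2 is 100 t km^-2
  expect_equal(district_mean(mp, poly)$mean_biomass_t_km2, 100)
  # single-cell polygon picks that cell's value
  mp$biomass$values[20, 1] <- 7   # cell centred (5, 5)
  one <- district_mean(mp, rect_polygon(0, 10, 0, 10))
  expect_equal(one$mean_biomass_t_km2, 7)
  expect_equal(one$n_cells, 1)
  # zero-biomass mires lower the mean monotonically when included
  lc <- lichen_grid(matrix(landcover_code("heath"), 20, 20), pixel_m = 10)
  lc$values[1:5, ] <- landcover_code("mire")
  mp$biomass$values[1:5, ] <- 0
  with_m <- district_mean(mp, poly, lc, include_mires = TRUE)
  without_m <- district_mean(mp, poly, lc, include_mires = FALSE)
  expect_lt(with_m$mean_biomass_t_km2, without_m$mean_biomass_t_km2)
  # weighted-mean oracle
  expect_equal(with_m$mean_biomass_t_km2,
               (without_m$mean_biomass_t_km2 * without_m$n_cells + 0) /
                 with_m$n_cells)
  expect_error(district_mean(mp, rect_polygon(500, 600, 500, 600)),
               "no map cells")
})

test_that("rescaling coefficients are 1 for flat scenes and decay on patchy ones", {
  reg <- fit_plot_regressions(tibble::tibble(
    grey_mean = c(40, 60, 80, 95), cover2d_pct = c(0, 36, 73, 100),
    biomass_g_m2 = c(0, 400, 800, 1100)))
  flat <- lichen_grid(matrix(70, 60, 60), pixel_m = 1)
  rc <- suppressWarnings(rescale_coefficients(flat, reg, c(10, 30, 60)))
  expect_equal(rc$coefficient, rep(1, 4), tolerance = 1e-12)
  expect_equal(rc$coefficient[rc$pixel_m == 1], 1)
  # isolated bright patches on a below-threshold matrix: averaging before
  # clamping loses them, brute-force aggregation oracle agrees
  v <- matrix(30, 60, 60)                 # below the zero-cover grey
  v[seq(5, 55, 10), seq(5, 55, 10)] <- 95 # bright single-pixel patches
  patchy <- lichen_grid(v, pixel_m = 1)
  rcp <- suppressWarnings(rescale_coefficients(patchy, reg, c(10, 30, 60)))
  expect_true(all(rcp$coefficient <= 1 + 1e-12))
  expect_true(all(diff(rcp$coefficient) <= 1e-12))
  expect_lt(rcp$coefficient[rcp$pixel_m == 60], 1)
  bio_at <- function(g) {
    p <- suppressWarnings(predict_maps(g, reg))
    mean(p$biomass$values)
  }
  oracle <- bio_at(grid_aggregate(patchy, 30)) / bio_at(patchy)
  expect_equal(rcp$coefficient[rcp$pixel_m == 30], oracle, tolerance = 1e-12)
  expect_error(suppressWarnings(rescale_coefficients(patchy, reg, c(7))),
               "not a multiple")
})

test_that("wMAPE matches its ratio-of-sums definition", {
  expect_equal(wmape(data.frame(observed = c(1, 2), reconstructed = c(1, 2))), 0)
  expect_equal(wmape(data.frame(observed = c(100, 200),
                                reconstructed = c(150, 150))), 1 / 3)
  # identity: wMAPE = MAE / mean(|O|)
  set.seed(3)
  o <- runif(20, 10, 100); s <- o + rnorm(20, 0, 5)
  df <- data.frame(observed = o, reconstructed = s)
  expect_equal(wmape(df), mean(abs(o - s)) / mean(abs(o)))
  expect_error(wmape(data.frame(observed = c(0, 0),
                                reconstructed = c(1, 1))), "zero")
})

test_that("the mapping chain round-trips district biomass on clean data", {
  # homogeneous mat thickness makes biomass an exact linear function of
  # grey, isolating the self-consistency of the mapping chain itself
  land <- generate_landscape(landscape_spec(
    extent_m = c(1000, 1000), base_pixel_m = 2,
    n_lakes = 6, n_fens = 3, n_sandpits = 5,
    patch_height_range = c(50, 50), seed = 42))
  g <- to_greyscale(render_scene(land, ideal_sensor()))
  plots <- extract_plot_grey(g, dplyr::bind_rows(
    generate_plots(land, site = "a", y_range = c(50, 470)),
    generate_plots(land, site = "b", y_range = c(530, 950))))
  reg <- fit_plot_regressions(dplyr::filter(plots, .data$landcover == "heath"))
  mp <- predict_maps(g, reg, land$landcover,
                     exclude = c("forest", "water", "sand"))
  truth_mp <- make_map_pair(land$cover$values, land$biomass$values,
                            pixel_m = land$spec$base_pixel_m)
  for (side in names(land$districts)) {
    pred <- district_mean(mp, land$districts[[side]], land$landcover)
    truth <- district_mean(truth_mp, land$districts[[side]], land$landcover)
    expect_equal(pred$mean_biomass_t_km2, truth$mean_biomass_t_km2,
                 tolerance = 0.05)
  }
})
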