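#' Configuration for the end-to-end reconstruction pipeline
#'
#' Collects every stage's settings with defaults sized for a desk-scale
#' run: a synthetic landscape, a sensor fleet spanning drone-like to
#' coarse-satellite resolutions, two plot campaigns (a training and a
#' held-out test site), zonal buffers, the rescaling diagnostic, and the
#' district biomass model with per-district censuses and loss parameters.
#'
#' @param landscape arguments for [landscape_spec()] (list) or a ready
#'   `landscape_spec`.
#' @param sensors list of [sensor_spec()]s; one must be named as
#'   `target_sensor` (the radiometric anchor) and one as `plot_sensor`
#'   (the high-resolution mosaic linking plots to grey levels).
#' @param target_sensor,plot_sensor names of the anchor and mosaic sensors.
#' @param train_site,test_site site labels for the two plot campaigns.
#' @param buffers_m zonal comparison buffers (m).
#' @param rescale_pixels_m pixel sizes for the rescaling diagnostic (m).
#' @param n_ft_points random points sampled per map for the landscape
#'   growth factor.
#' @param model_years years simulated by the biomass model.
#' @param districts per-district model settings: named list (sideA, sideB)
#'   of lists with `base_count`, `area_km2`, `occupancy_days`,
#'   `growth_rate`, `shocks`, `intake_t`, `true_loss`, `b0`.
#' @param recon_noise_sd observation noise of the synthetic reconstructed
#'   biomass history used for loss fitting.
#' @param recon_years years at which that history is observed.
#' @param seed master seed; every stage derives its stream from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(
    landscape = list(),
    sensors = NULL,
    target_sensor = "anchor-10m",
    plot_sensor = "drone-2m",
    train_site = "trainsite",
    test_site = "testsite",
    buffers_m = c(200, 1000),
    rescale_pixels_m = c(10, 30, 60),
    n_ft_points = 2000,
    model_years = 1946:2020,
    districts = list(
      sideA = list(base_count = 900, area_km2 = 300, occupancy_days = 365,
                   growth_rate = 0.012, shocks = c("1997" = 0.75, "2000" = 0.8),
                   intake_t = 0.338, true_loss = 0.069, b0 = 400),
      sideB = list(base_count = 2000, area_km2 = 300, occupancy_days = 157,
                   growth_rate = 0.015, shocks = NULL,
                   intake_t = 0.676, true_loss = 0.019, b0 = 400)
    ),
    recon_noise_sd = 0.1,
    recon_years = seq(1950, 2020, by = 10),
    seed = 1L) {
  if (!inherits(landscape, "landscape_spec")) {
    landscape <- do.call(landscape_spec,
                         utils::modifyList(list(seed = seed), landscape))
  }
  if (is.null(sensors)) {
    sensors <- list(
      sensor_spec("drone-2m", pixel_m = landscape$base_pixel_m,
                  gain = 2.1, offset = 14, noise_sd = 1.2, year = 2020L),
      sensor_spec("anchor-10m", pixel_m = 10, gain = 1, offset = 0,
                  noise_sd = 0, year = 2020L),
      sensor_spec("early-sat-60m", pixel_m = 60, gain = 0.06, offset = 25,
                  noise_sd = 0.35, bands = c("R", "G"), year = 1973L,
                  coverage_fraction = 1),
      sensor_spec("mid-sat-30m", pixel_m = 30, gain = 2.8, offset = 180,
                  noise_sd = 3, year = 1992L),
      sensor_spec("late-sat-10m", pixel_m = 10, gain = 1.4, offset = -8,
                  noise_sd = 1.5, year = 2009L)
    )
  }
  names(sensors) <- purrr::map_chr(sensors, "name")
  for (nm in c(target_sensor, plot_sensor)) {
    if (!nm %in% names(sensors)) {
      rlang::abort(sprintf("sensor '%s' not found in the sensor list", nm))
    }
  }
  structure(list(
    landscape = landscape, sensors = sensors,
    target_sensor = target_sensor, plot_sensor = plot_sensor,
    train_site = train_site, test_site = test_site,
    buffers_m = buffers_m, rescale_pixels_m = rescale_pixels_m,
    n_ft_points = n_ft_points, model_years = as.integer(model_years),
    districts = districts, recon_noise_sd = recon_noise_sd,
    recon_years = as.integer(recon_years), seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; `landscape` and
#' `districts` are taken as nested lists; sensors are built from a list of
#' [sensor_spec()] argument sets.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sensors)) {
    y$sensors <- purrr::map(y$sensors, ~ do.call(sensor_spec, .x))
  }
  if (!is.null(y$districts)) {
    y$districts <- purrr::map(y$districts, function(d) {
      if (!is.null(d$shocks)) d$shocks <- unlist(d$shocks)
      d
    })
  }
  do.call(pipeline_config, y)
}

#' Split plots by site and report held-out regression skill
#'
#' Trains the cover and biomass regressions on the training site only and
#' scores them on the held-out site: held-out R^2 is one minus the residual
#' sum of squares over the test plots divided by their total sum of
#' squares. Training p-values are the OLS slope F-tests.
#'
#' @param plots plot tibble with `site` and `grey_mean` columns.
#' @param train_site,test_site site labels present in `plots`.
#' @return A list: `regression` (fit on the training site) and `metrics`
#'   tibble (response, r2_train, r2_heldout, p_value_train, n_train,
#'   n_test).
#' @export
train_test_split_sites <- function(plots, train_site, test_site) {
  for (s in c(train_site, test_site)) {
    if (!any(plots$site == s)) rlang::abort(sprintf("site '%s' missing", s))
  }
  tr <- dplyr::filter(plots, .data$site == train_site)
  te <- dplyr::filter(plots, .data$site == test_site,
                      is.finite(.data$grey_mean))
  if (!nrow(te)) rlang::abort("test site has no usable plots")
  reg <- fit_plot_regressions(tr)
  heldout_r2 <- function(obs, pred) {
    sst <- sum((obs - mean(obs))^2)
    if (sst <= 0) return(NA_real_)
    1 - sum((obs - pred)^2) / sst
  }
  pv <- function(fit) {
    fs <- suppressWarnings(summary(fit)$fstatistic)
    unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  pred_cov <- reg$cover_intercept + reg$cover_slope * te$grey_mean
  pred_bio <- reg$biomass_intercept + reg$biomass_slope * te$grey_mean
  metrics <- tibble::tibble(
    response = c("cover2d_pct", "biomass_g_m2"),
    r2_train = c(reg$r2_cover, reg$r2_biomass),
    r2_heldout = c(heldout_r2(te$cover2d_pct, pred_cov),
                   heldout_r2(te$biomass_g_m2, pred_bio)),
    p_value_train = c(pv(reg$fit_cover), pv(reg$fit_biomass)),
    n_train = reg$n_plots, n_test = nrow(te)
  )
  list(regression = reg, metrics = metrics)
}

calibrate_scene_to_target <- function(grey, target_grey, areas, name) {
  src <- extract_reference_means(grey, areas)
  tgt <- extract_reference_means(target_grey, areas)
  obs <- reference_observations(src, tgt)
  model <- fit_calibration(obs, source = name, target = target_grey$name)
  list(model = model, calibrated = apply_calibration(grey, model))
}

#' Run the full reconstruction-and-model pipeline
#'
#' Executes, in dependency order: landscape generation, scene rendering
#' for every sensor, greyscale conversion, reference-area calibration to
#' the anchor scene (with the two-step local refinement for the
#' high-resolution mosaic), plot campaigns and the train/test regression
#' split, cover and biomass mapping per scene, zonal border comparisons,
#' district means, the rescaling diagnostic, landscape growth factors,
#' census generation, the biomass model with its variants, loss-parameter
#' fitting on a synthetic reconstructed history, and wMAPE validation of
#' the maps against the landscape truth. Bit-identical for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every report table is
#'   written as CSV, maps as `.asc`, and the config echoed to YAML.
#' @return A `run_report` list of tidy tables (see Details in the package
#'   vignette); carries the config hash.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  land <- stage("landscape", generate_landscape(config$landscape))
  scenes <- stage("render", purrr::map(config$sensors,
                                       ~ render_scene(land, .x)))
  greys <- stage("greyscale", purrr::map(scenes, to_greyscale))
  target_grey <- greys[[config$target_sensor]]

  calib <- stage("calibrate", {
    purrr::imap(greys[names(greys) != config$target_sensor], function(g, nm) {
      calibrate_scene_to_target(g, target_grey, land$reference_areas, nm)
    })
  })
  calibrated <- purrr::map(calib, "calibrated")
  calibrated[[config$target_sensor]] <- target_grey
  calibration_table <- purrr::map_dfr(calib, ~ glance(.x$model)) |>
    dplyr::mutate(pixel_m = purrr::map_dbl(config$sensors[.data$source], "pixel_m"),
                  year = purrr::map_int(config$sensors[.data$source],
                                        ~ as.integer(.x$year)),
                  .before = 1)

  # two-step refinement of the high-resolution mosaic against the anchor
  plot_grey <- stage("refine", {
    hr <- calibrated[[config$plot_sensor]]
    if (hr$pixel_m < target_grey$pixel_m) refine_local(hr, target_grey) else hr
  })

  plots <- stage("plots", dplyr::bind_rows(
    generate_plots(land, site = config$train_site,
                   y_range = c(0.05, 0.48) * land$spec$extent_m[2]),
    generate_plots(land, site = config$test_site,
                   y_range = c(0.52, 0.95) * land$spec$extent_m[2])
  ))
  plots <- stage("plot_grey", extract_plot_grey(plot_grey, plots))
  # regressions use heath plots only, as on treeless tundra field sites
  split <- stage("regression",
                 train_test_split_sites(
                   dplyr::filter(plots, .data$landcover == "heath"),
                   config$train_site, config$test_site))
  reg <- split$regression

  # zonal comparisons mask everything but heath; district-mean maps keep
  # mires (their dark surfaces clamp to zero biomass, the whole-district
  # convention used by the biomass model)
  maps <- stage("map", purrr::map(calibrated, function(g) {
    predict_maps(g, reg, land$landcover)
  }))
  maps_district <- stage("map_district", purrr::map(calibrated, function(g) {
    predict_maps(g, reg, land$landcover,
                 exclude = c("forest", "water", "sand"))
  }))

  zone_comparisons <- stage("compare_zones", purrr::map_dfr(maps, function(mp) {
    zonal_comparison(mp, land$border_line, config$buffers_m)
  }, .id = "source"))

  district_means <- stage("district_means", purrr::map_dfr(maps_district, function(mp) {
    purrr::imap_dfr(land$districts, function(poly, side) {
      dplyr::mutate(
        district_mean(mp, poly, land$landcover, include_mires = TRUE),
        side = side, .before = 1)
    })
  }, .id = "source"))

  rescale_table <- stage("rescale", {
    native <- plot_grey
    fac_ok <- config$rescale_pixels_m[
      config$rescale_pixels_m %% native$pixel_m == 0]
    rescale_coefficients(native, reg, fac_ok, land$landcover)
  })

  # landscape growth factors from the mapped biomass, one anchor per year
  ft_anchors <- stage("ft", {
    purrr::imap_dfr(maps_district, function(mp, nm) {
      v <- mp$biomass$values[!is.na(mp$biomass$values)]
      pts <- with_seed(seed_from(config$seed, "ft", nm),
                       sample(v, min(config$n_ft_points, length(v))))
      f <- tryCatch(landscape_factor(pts), error = function(e) NA_real_)
      tibble::tibble(source = nm,
                     year = as.integer(config$sensors[[nm]]$year), f = f)
    })
  })
  ft_ok <- dplyr::filter(ft_anchors, is.finite(.data$f))
  ft_series <- if (nrow(ft_ok)) {
    interpolate_factor(dplyr::distinct(ft_ok, .data$year, .keep_all = TRUE),
                       config$model_years)
  } else {
    tibble::tibble(year = config$model_years, f = 0.65,
                   provenance = "default")
  }

  model_out <- stage("model", purrr::imap(config$districts, function(dc, side) {
    census <- generate_census(config$model_years, dc$base_count, dc$area_km2,
                              dc$occupancy_days, dc$growth_rate, dc$shocks,
                              seed = seed_from(config$seed, "census", side))
    dens <- census_to_density(census)
    pars <- model_params(intake_t_per_reindeer_year = dc$intake_t,
                         loss_factor = dc$true_loss)
    traj <- purrr::map_dfr(MODEL_VARIANTS, function(v) {
      simulate_biomass(dc$b0, config$model_years, dens, ft_series, pars, v)
    })
    recon <- forward_reconstruction_series(
      pars, dens, ft_series, dc$b0, config$recon_noise_sd,
      config$recon_years, seed = seed_from(config$seed, "recon", side))
    fit <- fit_loss_parameter(recon, dc$b0, dens, ft_series, pars)
    list(census = census, densities = dens, trajectories = traj,
         reconstruction = recon, fit = fit)
  }))
  trajectories <- purrr::map_dfr(model_out,
                                 ~ dplyr::as_tibble(.x$trajectories),
                                 .id = "side")
  loss_fits <- purrr::map_dfr(model_out, ~ glance(.x$fit), .id = "side")
  loss_fits$true_loss <- purrr::map_dbl(config$districts, "true_loss")

  # validation: mapped district means against the landscape truth
  wmape_tbl <- stage("validate", {
    truth_map <- structure(list(biomass = land$biomass, cover = land$cover,
                                year = NA_integer_), class = "lichen_map_pair")
    truth <- purrr::imap_dfr(land$districts, function(poly, side) {
      dplyr::mutate(district_mean(truth_map, poly, land$landcover),
                    side = side, .before = 1)
    })
    pairs <- dplyr::inner_join(
      dplyr::select(district_means, "source", "side",
                    reconstructed = "mean_biomass_t_km2"),
      dplyr::select(truth, "side", observed = "mean_biomass_t_km2"),
      by = "side", relationship = "many-to-one")
    tibble::tibble(wmape = wmape(pairs), n_pairs = nrow(pairs))
  })

  report <- structure(list(
    calibration_table = calibration_table,
    regression_metrics = split$metrics,
    regression = reg,
    zone_comparisons = zone_comparisons,
    district_means = district_means,
    rescale_table = rescale_table,
    ft_anchors = ft_anchors,
    ft_series = ft_series,
    trajectories = trajectories,
    loss_fits = loss_fits,
    wmape = wmape_tbl,
    maps = maps,
    plots = dplyr::select(plots, -"mask"),
    seed = config$seed,
    config_hash = rlang::hash(config)
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, config, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, config %s\n", x$seed, x$config_hash))
  cat(sprintf("  calibrations: %d scenes, R^2 %.2f-%.2f\n",
              nrow(x$calibration_table), min(x$calibration_table$r_squared),
              max(x$calibration_table$r_squared)))
  cat(sprintf("  regression R^2: cover %.2f, biomass %.2f (held-out %.2f, %.2f)\n",
              x$regression_metrics$r2_train[1], x$regression_metrics$r2_train[2],
              x$regression_metrics$r2_heldout[1],
              x$regression_metrics$r2_heldout[2]))
  cat(sprintf("  fitted loss: %s\n",
              paste(sprintf("%s l=%.3f (true %.3f)", x$loss_fits$side,
                            x$loss_fits$l_hat, x$loss_fits$true_loss),
                    collapse = ", ")))
  cat(sprintf("  mapping wMAPE vs truth: %.1f%%\n", 100 * x$wmape$wmape[1]))
  invisible(x)
}

write_run_report <- function(report, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("calibration_table", "regression_metrics", "zone_comparisons",
            "district_means", "rescale_table", "ft_series", "trajectories",
            "loss_fits", "wmape", "plots")
  for (nm in tabs) {
    readr::write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  for (nm in names(report$maps)) {
    write_asc(report$maps[[nm]]$biomass,
              file.path(out_dir, paste0("biomass_", nm, ".asc")))
  }
  cfg <- config
  cfg$landscape <- unclass(cfg$landscape)
  cfg$sensors <- purrr::map(cfg$sensors, unclass)
  yaml::write_yaml(c(unclass(cfg), list(config_hash = report$config_hash)),
                   file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}
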