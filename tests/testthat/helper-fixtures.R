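# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# 1 km^2 landscape at 2 m pixels with a reduced reference inventory;
# memoised because several test files reuse it
test_landscape <- function(seed = 42) {
  key <- paste0("land_", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_landscape(landscape_spec(
      extent_m = c(1000, 1000), base_pixel_m = 2,
      n_lakes = 6, n_fens = 3, n_sandpits = 5, seed = seed))
  }
  fixture_env[[key]]
}

ideal_sensor <- function(pixel_m = 2, year = 2020L) {
  sensor_spec("ideal", pixel_m = pixel_m, gain = 1, offset = 0,
              noise_sd = 0, year = year)
}

# flat densities / factors covering a year range
flat_density <- function(years, d) tibble::tibble(year = years, d = d)
flat_ft <- function(years, f) tibble::tibble(year = years, f = f)

# hand-built map pair on a uniform grid (for zonal/district oracles)
make_map_pair <- function(cover, biomass, pixel_m = 10, year = NA_integer_) {
  structure(list(
    cover = lichen_grid(cover, 0, 0, pixel_m, year = year),
    biomass = lichen_grid(biomass, 0, 0, pixel_m, year = year),
    excluded_mask = lichen_grid(matrix(0, nrow(cover), ncol(cover)),
                                0, 0, pixel_m),
    year = year
  ), class = "lichen_map_pair")
}
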