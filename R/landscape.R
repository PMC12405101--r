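#' Specification of a synthetic fell landscape
#'
#' Describes a planar tundra-heath domain split by a north--south border
#' fence, with bright forage-lichen patches on a darker vegetated matrix,
#' radiometrically stable dark (lakes, open fens) and bright (sandpits)
#' reference areas, and a simple heath/forest/mire/water land-cover mosaic.
#' The defaults emulate the structure of a Fennoscandian border-fence study
#' area: 24 lakes, 9 open fens and 15 sandpits as calibration references,
#' and a land-cover mix dominated by forest (41.1\%) and peatland (28.2\%).
#'
#' @param extent_m width and height of the domain in metres (length-2).
#' @param base_pixel_m native resolution of the truth rasters (m).
#' @param lichen_patch_density lichen patches per square kilometre.
#' @param patch_biomass_range min/max peak dry biomass of a patch (g m^-2);
#'   must lie within [0, 2114], the biomass at 100\% 2D cover under the
#'   volume-to-mass conversion used throughout.
#' @param matrix_biomass dry biomass of the worn heath matrix (g m^-2).
#' @param n_lakes,n_fens,n_sandpits counts of reference features.
#' @param border_x easting of the border fence (m); default mid-domain.
#' @param landcover_fractions named proportions of heath/forest/mire/water,
#'   summing to 1.
#' @param patch_height_range min/max lichen mat thickness in patches (mm).
#' @param matrix_height_mm mat thickness of the heath matrix (mm).
#' @param seed integer seed; every derived artefact is a pure function of
#'   the full specification including this seed.
#' @return A `landscape_spec` list.
#' @export
landscape_spec <- function(extent_m = c(3000, 3000),
                           base_pixel_m = 2,
                           lichen_patch_density = 25,
                           patch_biomass_range = c(200, 2000),
                           matrix_biomass = 20,
                           n_lakes = 24, n_fens = 9, n_sandpits = 15,
                           border_x = extent_m[1] / 2,
                           landcover_fractions = c(heath = 0.290,
                                                   forest = 0.411,
                                                   mire = 0.282,
                                                   water = 0.017),
                           patch_height_range = c(40, 60),
                           matrix_height_mm = 50,
                           seed = 1L) {
  if (length(extent_m) == 1) extent_m <- rep(extent_m, 2)
  if (any(extent_m <= 0)) rlang::abort("extent_m must be positive")
  if (base_pixel_m <= 0) rlang::abort("base_pixel_m must be positive")
  if (abs(sum(landcover_fractions) - 1) > 1e-9) {
    rlang::abort("landcover_fractions must sum to 1")
  }
  if (patch_biomass_range[1] < 0 || patch_biomass_range[2] > BIOMASS_CAP_FULL_COVER ||
      patch_biomass_range[1] > patch_biomass_range[2]) {
    rlang::abort(sprintf("patch_biomass_range must lie within [0, %s]",
                         BIOMASS_CAP_FULL_COVER))
  }
  need <- c("heath", "forest", "mire", "water")
  if (!all(need %in% names(landcover_fractions))) {
    rlang::abort("landcover_fractions needs heath/forest/mire/water entries")
  }
  structure(list(
    extent_m = extent_m, base_pixel_m = base_pixel_m,
    lichen_patch_density = lichen_patch_density,
    patch_biomass_range = patch_biomass_range,
    matrix_biomass = matrix_biomass,
    n_lakes = n_lakes, n_fens = n_fens, n_sandpits = n_sandpits,
    border_x = border_x,
    landcover_fractions = landcover_fractions[need],
    patch_height_range = patch_height_range,
    matrix_height_mm = matrix_height_mm,
    seed = as.integer(seed)
  ), class = "landscape_spec")
}

# biomass (g m^-2) of a 100% 2D cover lichen mat at the upper mat thickness
# used for mapping caps: 22 g dm^-3 * 9.6 dm^3 m^-2 ... kept as the printed
# mapping cap so patch specs cannot exceed what a map may represent.
BIOMASS_CAP_FULL_COVER <- 2114

# land-cover codes shared by all grids
LANDCOVER_LEVELS <- c(heath = 1, forest = 2, mire = 3, water = 4, sand = 5)

# intrinsic reflectance model (grey level of an ideal, distortion-free
# sensor): piecewise-linear in 2D lichen cover on vegetated ground between
# a dark matrix value and a bright full-lichen value; class constants for
# water, fen/mire and sand.
REFL_VEG_DARK   <- 40   # vegetated ground, 0 % lichen cover
REFL_VEG_BRIGHT <- 95   # continuous lichen mat, 100 % cover
REFL_WATER      <- 11
REFL_MIRE       <- 16
REFL_SAND       <- 95.5

intrinsic_reflectance <- function(cover_pct) {
  REFL_VEG_DARK + (REFL_VEG_BRIGHT - REFL_VEG_DARK) * cover_pct / 100
}

place_discs <- function(n, r_mean, extent, avoid, label, max_tries = 4000) {
  # rejection-sample non-overlapping disc centres; avoid is a growing
  # tibble of (x, y, r) already placed
  out <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- r_mean * stats::runif(1, 0.7, 1.3)
      x <- stats::runif(1, r + 5, extent[1] - r - 5)
      y <- stats::runif(1, r + 5, extent[2] - r - 5)
      if (nrow(avoid) == 0 ||
          all(sqrt((avoid$x - x)^2 + (avoid$y - y)^2) > avoid$r + r + 10)) {
        avoid <- dplyr::bind_rows(avoid, tibble::tibble(x = x, y = y, r = r))
        out[[i]] <- c(x = x, y = y, r = r)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rlang::abort(sprintf(
        "domain %g x %g m too small to place %d non-overlapping %s (placed %d)",
        extent[1], extent[2], n, label, i - 1))
    }
  }
  list(placed = do.call(rbind, out), avoid = avoid)
}

#' Generate a synthetic landscape with known lichen truth
#'
#' Builds the ground truth that real campaigns can never observe: co-located
#' rasters of 2D lichen cover (\%), mat thickness (mm) and dry biomass
#' (g m^-2, linked everywhere by biomass = 22 * (cover/100) * height), a
#' land-cover mosaic, radiometrically stable reference-area polygons with
#' fixed intrinsic reflectances, the border fence polyline, and one district
#' polygon per side of the fence. Deterministic for a fixed spec.
#'
#' @param spec a [landscape_spec()].
#' @return A `true_landscape` list: grids `biomass`, `cover`, `height`,
#'   `landcover`, `reflectance`; tibble `reference_areas` (id, class,
#'   reflectance, polygon list-column); `border_line` matrix; named list
#'   `districts` (sideA = west, sideB = east); and the `spec`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(spec$seed, {
    px <- spec$base_pixel_m
    nc <- round(spec$extent_m[1] / px)
    nr <- round(spec$extent_m[2] / px)
    if (nc < 8 || nr < 8) rlang::abort("domain too small for base_pixel_m")

    # --- land cover: blocky random field thresholded at the forest and
    # mire target fractions; reference features override it below
    blob_factor <- max(1L, as.integer(round(150 / px)))
    cf_r <- ceiling(nr / blob_factor); cf_c <- ceiling(nc / blob_factor)
    field <- matrix(stats::rnorm(cf_r * cf_c), cf_r, cf_c)
    field <- field[rep(seq_len(cf_r), each = blob_factor)[seq_len(nr)],
                   rep(seq_len(cf_c), each = blob_factor)[seq_len(nc)]]
    fr <- spec$landcover_fractions
    q_forest <- stats::quantile(field, fr[["forest"]])
    q_mire <- stats::quantile(field, fr[["forest"]] + fr[["mire"]])
    landcover <- matrix(LANDCOVER_LEVELS[["heath"]], nr, nc)
    landcover[field <= q_forest] <- LANDCOVER_LEVELS[["forest"]]
    landcover[field > q_forest & field <= q_mire] <- LANDCOVER_LEVELS[["mire"]]

    # --- reference areas: lakes ~2.2 ha, fens and sandpits ~0.3 ha
    avoid <- tibble::tibble(x = numeric(), y = numeric(), r = numeric())
    lk <- place_discs(spec$n_lakes, sqrt(22000 / pi), spec$extent_m, avoid,
                      "lakes")
    fn <- place_discs(spec$n_fens, sqrt(3000 / pi), spec$extent_m, lk$avoid,
                      "fens")
    sd_ <- place_discs(spec$n_sandpits, sqrt(3000 / pi), spec$extent_m,
                       fn$avoid, "sandpits")
    ref_centres <- sd_$avoid

    mk_refs <- function(mat, class, code, refl_mean, refl_sd, prefix) {
      if (is.null(mat)) return(tibble::tibble())
      tibble::tibble(
        id = sprintf("%s%02d", prefix, seq_len(nrow(mat))),
        class = class,
        feature = prefix,
        reflectance = pmax(1, stats::rnorm(nrow(mat), refl_mean, refl_sd)),
        x = mat[, "x"], y = mat[, "y"], r = mat[, "r"],
        landcover = code
      )
    }
    refs <- dplyr::bind_rows(
      mk_refs(lk$placed, "dark", LANDCOVER_LEVELS[["water"]], REFL_WATER, 1.2, "lake"),
      mk_refs(fn$placed, "dark", LANDCOVER_LEVELS[["mire"]], REFL_MIRE, 1.2, "fen"),
      mk_refs(sd_$placed, "bright", LANDCOVER_LEVELS[["sand"]], REFL_SAND, 1.5, "sand")
    )
    refs$polygon <- purrr::pmap(list(refs$x, refs$y, refs$r),
                                function(x, y, r) disc_polygon(x, y, r))

    # carrier grid for polygon rasterisation
    g0 <- lichen_grid(matrix(0, nr, nc), 0, 0, px)
    ref_masks <- purrr::map(refs$polygon, ~ cells_in_polygon(g0, .x))
    for (i in seq_len(nrow(refs))) landcover[ref_masks[[i]]] <- refs$landcover[i]

    # --- lichen cover and mat-height truth
    cover <- matrix(0, nr, nc)
    height <- matrix(0, nr, nc)
    veg <- landcover %in% c(LANDCOVER_LEVELS[["heath"]], LANDCOVER_LEVELS[["forest"]])
    if (spec$matrix_biomass > 0) {
      m_cov <- min(100, 100 * spec$matrix_biomass / (22 * spec$matrix_height_mm))
      cover[veg] <- m_cov
      height[veg] <- spec$matrix_height_mm
    }

    area_km2 <- prod(spec$extent_m) / 1e6
    n_patch <- round(spec$lichen_patch_density * area_km2)
    heath <- landcover == LANDCOVER_LEVELS[["heath"]]
    cc <- grid_coords(g0)
    if (n_patch > 0) {
      for (p in seq_len(n_patch)) {
        # keep patch centres clear of reference areas so calibration
        # targets stay radiometrically pure
        for (try in seq_len(2000)) {
          pr <- stats::runif(1, 30, 120)
          pxc <- stats::runif(1, 0, spec$extent_m[1])
          pyc <- stats::runif(1, 0, spec$extent_m[2])
          if (all(sqrt((ref_centres$x - pxc)^2 + (ref_centres$y - pyc)^2) >
                  ref_centres$r + pr)) break
          if (try == 2000) rlang::abort(
            "domain too crowded with reference areas to place lichen patches")
        }
        b_peak <- stats::runif(1, spec$patch_biomass_range[1],
                               spec$patch_biomass_range[2])
        h_patch <- stats::runif(1, spec$patch_height_range[1],
                                spec$patch_height_range[2])
        c_peak <- min(100, 100 * b_peak / (22 * h_patch))
        # parabolic taper to the matrix at the patch edge
        ci <- which(abs(cc$x - pxc) <= pr)
        ri <- which(abs(cc$y - pyc) <= pr)
        if (!length(ci) || !length(ri)) next
        dx <- cc$x[ci] - pxc; dy <- cc$y[ri] - pyc
        d2 <- outer(dy^2, dx^2, `+`)
        prof <- c_peak * pmax(0, 1 - d2 / pr^2)
        sub_heath <- heath[ri, ci, drop = FALSE]
        sub_cov <- cover[ri, ci, drop = FALSE]
        upd <- sub_heath & prof > sub_cov
        sub_cov[upd] <- prof[upd]
        cover[ri, ci] <- sub_cov
        sub_h <- height[ri, ci, drop = FALSE]
        sub_h[upd] <- h_patch
        height[ri, ci] <- sub_h
      }
    }
    nonveg <- !veg
    cover[nonveg] <- 0
    height[nonveg] <- 0
    biomass <- 22 * (cover / 100) * height

    # --- intrinsic reflectance truth
    refl <- intrinsic_reflectance(cover)
    refl[landcover == LANDCOVER_LEVELS[["water"]]] <- REFL_WATER
    refl[landcover == LANDCOVER_LEVELS[["mire"]]] <- REFL_MIRE
    refl[landcover == LANDCOVER_LEVELS[["sand"]]] <- REFL_SAND
    for (i in seq_len(nrow(refs))) refl[ref_masks[[i]]] <- refs$reflectance[i]

    border_line <- rbind(c(spec$border_x, spec$extent_m[2]),
                         c(spec$border_x, 0))
    districts <- list(
      sideA = rect_polygon(0, spec$border_x, 0, spec$extent_m[2]),
      sideB = rect_polygon(spec$border_x, spec$extent_m[1], 0, spec$extent_m[2])
    )

    structure(list(
      biomass = lichen_grid(biomass, 0, 0, px, name = "biomass_truth"),
      cover = lichen_grid(cover, 0, 0, px, name = "cover_truth"),
      height = lichen_grid(height, 0, 0, px, name = "height_truth"),
      landcover = lichen_grid(landcover, 0, 0, px, name = "landcover"),
      reflectance = lichen_grid(refl, 0, 0, px, name = "intrinsic_reflectance"),
      reference_areas = dplyr::select(refs, -landcover),
      border_line = border_line,
      districts = districts,
      spec = spec
    ), class = "true_landscape")
  })
}

#' @export
print.true_landscape <- function(x, ...) {
  cat(sprintf(
    "<true_landscape> %g x %g m at %g m pixels; %d reference areas; seed %d\n",
    x$spec$extent_m[1], x$spec$extent_m[2], x$spec$base_pixel_m,
    nrow(x$reference_areas), x$spec$seed))
  invisible(x)
}

#' Land-cover code for a class name
#' @param class one of "heath", "forest", "mire", "water", "sand".
#' @return integer code used in land-cover grids.
#' @export
landcover_code <- function(class) {
  unname(LANDCOVER_LEVELS[match.arg(class, names(LANDCOVER_LEVELS),
                                    several.ok = TRUE)])
}
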