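#' Planar single-band raster grid
#'
#' A minimal georeferenced raster: a numeric matrix on a regular planar grid
#' (row 1 = northernmost row), with an origin, a square pixel size in metres,
#' and `NA` as the nodata value. All scenes, truth layers and lichen maps in
#' this package are `lichen_grid` objects.
#'
#' @param values numeric matrix; row 1 is the northern edge.
#' @param xmin,ymin planar coordinates (m) of the lower-left corner.
#' @param pixel_m square pixel size in metres.
#' @param year acquisition year (optional).
#' @param name source label (optional).
#' @return A `lichen_grid` object.
#' @export
lichen_grid <- function(values, xmin = 0, ymin = 0, pixel_m,
                        year = NA_integer_, name = NA_character_) {
  stopifnot(is.matrix(values), is.numeric(pixel_m), pixel_m > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, pixel_m = pixel_m,
         year = year, name = name),
    class = "lichen_grid"
  )
}

#' @export
print.lichen_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<lichen_grid> %d x %d cells, %.3g m pixels, extent [%g, %g] x [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$pixel_m,
    x$xmin, x$xmin + ncol(x$values) * x$pixel_m,
    x$ymin, x$ymin + nrow(x$values) * x$pixel_m))
  if (length(v)) {
    cat(sprintf("  valid: %d cells, range [%.4g, %.4g]", length(v),
                min(v), max(v)))
  } else {
    cat("  all nodata")
  }
  if (!is.na(x$year)) cat(sprintf("  year: %s", x$year))
  if (!is.na(x$name)) cat(sprintf("  source: %s", x$name))
  cat("\n")
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param g a `lichen_grid`.
#' @return list with `x` (length ncol, west to east) and `y` (length nrow,
#'   north to south) cell-centre coordinates in metres.
#' @export
grid_coords <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  list(
    x = g$xmin + (seq_len(nc) - 0.5) * g$pixel_m,
    y = g$ymin + (nr - seq_len(nr) + 0.5) * g$pixel_m
  )
}

#' @importFrom tibble as_tibble tibble
#' @exportS3Method
as_tibble.lichen_grid <- function(x, ...) {
  cc <- grid_coords(x)
  tibble::tibble(
    x = rep(cc$x, each = nrow(x$values)),
    y = rep(cc$y, times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

grid_compatible <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$pixel_m),
                     c(b$xmin, b$ymin, b$pixel_m)))
}

#' @export
Ops.lichen_grid <- function(e1, e2) {
  if (inherits(e1, "lichen_grid") && inherits(e2, "lichen_grid")) {
    if (!grid_compatible(e1, e2)) {
      rlang::abort("grids are not aligned (dimensions/origin/pixel differ)")
    }
    out <- e1
    out$values <- get(.Generic)(e1$values, e2$values)
  } else if (inherits(e1, "lichen_grid")) {
    out <- e1
    out$values <- get(.Generic)(e1$values, e2)
  } else {
    out <- e2
    out$values <- get(.Generic)(e1, e2$values)
  }
  out
}

#' Aggregate a grid to a coarser pixel size (block mean)
#'
#' Coarse cell values are the unweighted mean of the native cells whose
#' centres fall inside the coarse pixel; cells that are all nodata give
#' nodata. The factor must divide both grid dimensions.
#'
#' @param g a `lichen_grid`.
#' @param factor integer aggregation factor (coarse pixel = factor * native).
#' @param na_rm drop nodata native cells from the mean (default `TRUE`).
#' @return A `lichen_grid` at `factor * pixel_m` resolution.
#' @export
grid_aggregate <- function(g, factor, na_rm = TRUE) {
  factor <- as.integer(factor)
  nr <- nrow(g$values); nc <- ncol(g$values)
  if (factor < 1) rlang::abort("aggregation factor must be >= 1")
  if (factor == 1) return(g)
  if (nr %% factor != 0 || nc %% factor != 0) {
    rlang::abort(sprintf(
      "aggregation factor %d is not commensurate with grid %d x %d",
      factor, nr, nc))
  }
  v <- g$values
  # sum within row blocks, then column blocks; track valid counts for NA
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  rsum <- rowsum(v0, rep(seq_len(nr %/% factor), each = factor))
  rcnt <- rowsum(ok + 0, rep(seq_len(nr %/% factor), each = factor))
  csum <- t(rowsum(t(rsum), rep(seq_len(nc %/% factor), each = factor)))
  ccnt <- t(rowsum(t(rcnt), rep(seq_len(nc %/% factor), each = factor)))
  out <- csum / ccnt
  if (!na_rm) out[ccnt < factor^2] <- NA_real_
  out[ccnt == 0] <- NA_real_
  dimnames(out) <- NULL
  lichen_grid(out, g$xmin, g$ymin, g$pixel_m * factor, g$year, g$name)
}

#' Disaggregate a grid to a finer pixel size (block-constant)
#'
#' Each coarse cell value is replicated over the finer cells it contains
#' (nearest-cell upsampling).
#'
#' @param g a `lichen_grid`.
#' @param factor integer refinement factor.
#' @return A `lichen_grid` at `pixel_m / factor` resolution.
#' @export
grid_disaggregate <- function(g, factor) {
  factor <- as.integer(factor)
  if (factor < 1) rlang::abort("factor must be >= 1")
  if (factor == 1) return(g)
  v <- g$values
  out <- v[rep(seq_len(nrow(v)), each = factor),
           rep(seq_len(ncol(v)), each = factor), drop = FALSE]
  lichen_grid(out, g$xmin, g$ymin, g$pixel_m / factor, g$year, g$name)
}

#' Write / read a grid as an ESRI ASCII raster (.asc)
#'
#' Plain-text interchange format; nodata is written as -9999.
#'
#' @param g a `lichen_grid`.
#' @param path file path.
#' @return `write_asc` returns `path` invisibly; `read_asc` a `lichen_grid`.
#' @export
write_asc <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g$values)),
    sprintf("nrows %d", nrow(g$values)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$pixel_m),
    "NODATA_value -9999"), con)
  v <- g$values
  v[is.na(v)] <- -9999
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA_real_
  lichen_grid(v, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]])
}

#' Logical mask of cells inside a polygon
#'
#' Pixel-in-polygon rule is centre containment (standard zonal-statistics
#' convention): a cell belongs to the polygon iff its centre does.
#'
#' @param g a `lichen_grid`.
#' @param poly two-column matrix (x, y) of polygon vertices (open ring).
#' @return logical matrix with the grid's dimensions.
#' @export
cells_in_polygon <- function(g, poly) {
  poly <- as.matrix(poly)
  cc <- grid_coords(g)
  nr <- nrow(g$values); nc <- ncol(g$values)
  # restrict to the polygon bounding box before the point-in-polygon test
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  ci <- which(cc$x >= xr[1] & cc$x <= xr[2])
  ri <- which(cc$y >= yr[1] & cc$y <= yr[2])
  out <- matrix(FALSE, nr, nc)
  if (!length(ci) || !length(ri)) return(out)
  px <- rep(cc$x[ci], each = length(ri))
  py <- rep(cc$y[ri], times = length(ci))
  out[ri, ci] <- matrix(point_in_polygon(px, py, poly),
                        nrow = length(ri), ncol = length(ci))
  out
}

#' Mean of valid grid cells whose centres fall inside a polygon
#'
#' @inheritParams cells_in_polygon
#' @return list with `mean` (NA when no valid cell) and `n` valid cells.
#' @export
polygon_mean <- function(g, poly) {
  inside <- cells_in_polygon(g, poly)
  v <- g$values[inside]
  v <- v[!is.na(v)]
  list(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
}
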