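# Minimal planar geometry used by the zonal and reference-area operations.
# Grids are axis-aligned and polygons are simple rings, so ray casting and
# point-segment distances are all that is needed.

#' Point-in-polygon test (ray casting)
#'
#' @param px,py point coordinates (vectors of equal length).
#' @param poly two-column matrix (x, y) of polygon vertices, open ring.
#' @return logical vector; boundary points count as inside on the lower/left
#'   edges (even-odd rule).
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Distance from points to a polyline, with side labels
#'
#' Euclidean distance to the nearest segment; the side is the sign of the
#' cross product with the nearest segment's direction ("B" = left of the
#' oriented line, "A" = right). The synthetic border fence runs north to
#' south, so side A is west (Finland-analogue) and side B east
#' (Norway-analogue).
#'
#' @param px,py point coordinates.
#' @param line two-column matrix (x, y) of polyline vertices.
#' @return list with numeric `dist` and character `side` ("A"/"B").
#' @export
polyline_distance <- function(px, py, line) {
  line <- as.matrix(line)
  ns <- nrow(line) - 1
  if (ns < 1) rlang::abort("polyline needs at least two vertices")
  best <- rep(Inf, length(px))
  cross_at_best <- numeric(length(px))
  for (s in seq_len(ns)) {
    x1 <- line[s, 1]; y1 <- line[s, 2]
    x2 <- line[s + 1, 1]; y2 <- line[s + 1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2)) else 0
    ex <- px - (x1 + t * dx); ey <- py - (y1 + t * dy)
    d <- sqrt(ex * ex + ey * ey)
    cr <- dx * (py - y1) - dy * (px - x1)
    upd <- d < best
    best[upd] <- d[upd]
    cross_at_best[upd] <- cr[upd]
  }
  list(dist = best, side = ifelse(cross_at_best >= 0, "B", "A"))
}

#' Regular polygon approximating a disc
#'
#' @param cx,cy centre; @param r radius (m); @param n vertex count.
#' @return two-column matrix (x, y).
#' @export
disc_polygon <- function(cx, cy, r, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Axis-aligned rectangle polygon
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds (m).
#' @return two-column matrix (x, y).
#' @export
rect_polygon <- function(xmin, xmax, ymin, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' their (spec, seed) arguments without disturbing the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stable small-integer hash of a string, for deriving sub-stream seeds
seed_from <- function(seed, ...) {
  extra <- paste(unlist(list(...)), collapse = "|")
  h <- sum(utf8ToInt(extra) * (seq_len(nchar(extra)) %% 97 + 1))
  (as.integer(seed) * 2654435L + as.integer(h %% 1000003)) %% 2147483647L
}
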