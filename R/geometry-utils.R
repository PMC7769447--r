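# Low-level planar geometry helpers on the ring representation
# (ring = list(x, y), open; positive shoelace = exterior, negative = hole).

#' Signed area of one ring (shoelace)
#' @param ring list with numeric `x`, `y` (open ring).
#' @return signed area; positive for counter-clockwise rings.
#' @keywords internal
ringArea <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  if (n < 3) return(0)
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

# total area of a patch geometry (holes carry negative sign)
geomArea <- function(geom) sum(vapply(geom, ringArea, numeric(1)))

# force ring orientation; ccw = TRUE -> positive signed area
orientRing <- function(ring, ccw = TRUE) {
  a <- ringArea(ring)
  if ((ccw && a < 0) || (!ccw && a > 0))
    list(x = rev(ring$x), y = rev(ring$y))
  else ring
}

# drop a repeated closing vertex, if present
openRing <- function(ring) {
  n <- length(ring$x)
  if (n > 1 && ring$x[1] == ring$x[n] && ring$y[1] == ring$y[n])
    list(x = ring$x[-n], y = ring$y[-n])
  else ring
}

geomBBox <- function(geom) {
  xs <- unlist(lapply(geom, `[[`, "x"), use.names = FALSE)
  ys <- unlist(lapply(geom, `[[`, "y"), use.names = FALSE)
  c(min(xs), min(ys), max(xs), max(ys))
}

layerBBox <- function(layer) {
  bb <- vapply(layer@geometry, geomBBox, numeric(4))
  c(min(bb[1, ]), min(bb[2, ]), max(bb[3, ]), max(bb[4, ]))
}

# axis-aligned rectangle as a CCW ring
rectRing <- function(xmin, ymin, xmax, ymax) {
  list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# does the (open) ring intersect itself? O(V^2) segment-pair test,
# skipping adjacent segments which legitimately share an endpoint
ringSelfIntersects <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  if (n < 4) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(n - 2)) {
    js <- seq.int(i + 2, n)
    if (i == 1) js <- js[js != n]  # first and last segment are adjacent
    for (j in js) {
      if (segmentsCross(x[i], y[i], x2[i], y2[i], x[j], y[j], x2[j], y2[j]))
        return(TRUE)
    }
  }
  FALSE
}

segmentsCross <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  o <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- o(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- o(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- o(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- o(p1x, p1y, p2x, p2y, q2x, q2y)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on <- function(px, py, ax, ay, bx, by)
    min(ax, bx) <= px && px <= max(ax, bx) &&
    min(ay, by) <= py && py <= max(ay, by)
  (d1 == 0 && on(p1x, p1y, q1x, q1y, q2x, q2y)) ||
    (d2 == 0 && on(p2x, p2y, q1x, q1y, q2x, q2y)) ||
    (d3 == 0 && on(q1x, q1y, p1x, p1y, p2x, p2y)) ||
    (d4 == 0 && on(q2x, q2y, p1x, p1y, p2x, p2y))
}

# even-odd point-in-geometry test (holes respected)
pointInGeom <- function(px, py, geom) {
  inside <- FALSE
  for (ring in geom) {
    x <- ring$x; y <- ring$y
    n <- length(x)
    j <- n
    for (i in seq_len(n)) {
      if ((y[i] > py) != (y[j] > py)) {
        xint <- x[i] + (py - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
        if (px < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

# centroid of a patch geometry (area-weighted over rings, holes negative)
geomCentroid <- function(geom) {
  cx <- 0; cy <- 0; atot <- 0
  for (ring in geom) {
    x <- ring$x; y <- ring$y
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    a <- 0.5 * sum(cr)
    if (a == 0) next
    cx <- cx + sum((x + xn) * cr) / 6
    cy <- cy + sum((y + yn) * cr) / 6
    atot <- atot + a
  }
  if (atot == 0) {
    xs <- unlist(lapply(geom, `[[`, "x"))
    ys <- unlist(lapply(geom, `[[`, "y"))
    return(c(mean(xs), mean(ys)))
  }
  c(cx / atot, cy / atot)
}

# is any ring of the geometry invalid (self-intersecting)?
geomIsValid <- function(geom) !any(vapply(geom, ringSelfIntersects, logical(1)))

#' Construct a PatchLayer from ring geometries
#'
#' Low-level constructor: computes areas from the (oriented) ring
#' geometry and validates the object. Exterior rings must be
#' counter-clockwise (positive shoelace area), holes clockwise.
#'
#' @param geometry list of patch geometries, each a list of rings
#'   (`list(x, y)`, open).
#' @param patchId integer vector of unique ids.
#' @param crs optional CRS description string.
#' @return a [PatchLayer-class].
#' @export
newPatchLayer <- function(geometry, patchId, crs = NA_character_) {
  area <- vapply(geometry, geomArea, numeric(1))
  # invalid (self-intersecting) rings can have degenerate signed area;
  # fall back to the even-odd covered area so the layer can be held
  # prior to repairAndClip()
  for (i in which(!is.finite(area) | area <= 0)) {
    sim <- tryCatch(
      polyclip::polysimplify(geometry[[i]], filltype = "evenodd",
                             eps = clipperEps(geometry[[i]])),
      error = function(e) NULL)
    if (length(sim))
      area[i] <- sum(vapply(sim, ringArea, numeric(1)))
  }
  methods::new("PatchLayer", geometry = geometry,
               patchId = as.integer(patchId), area = area, crs = crs)
}

# integer-snapping resolution for Clipper operations: fine enough that
# snapping is negligible (1e-12 of the coordinate span) while staying
# far inside Clipper's 62-bit integer range
clipperEps <- function(...) {
  xs <- range(unlist(lapply(unlist(list(...), recursive = FALSE),
                            `[[`, "x")))
  ys <- range(unlist(lapply(unlist(list(...), recursive = FALSE),
                            `[[`, "y")))
  max(diff(xs), diff(ys), 1e-6) * 1e-12
}
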