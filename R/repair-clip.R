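#' Repair invalid geometries and clip to a boundary
#'
#' Fixes self-intersecting rings (e.g. bow-tie polygons) by resolving
#' each patch into the simple polygon(s) covering the same region
#' (even-odd fill rule, via the Clipper library in \pkg{polyclip}), and
#' optionally intersects every patch with a boundary polygon, dropping
#' patches whose intersection is empty. Areas are recomputed from the
#' repaired/clipped geometry.
#'
#' @param layer a [PatchLayer-class].
#' @param boundary optional boundary geometry: a list of rings (as in
#'   [PatchLayer-class] geometries) or a single ring `list(x, y)`.
#'   Repaired with the same even-odd rule before use.
#' @return a [PatchLayer-class] with valid geometry; patch ids of
#'   surviving patches are preserved.
#' @examples
#' bow <- list(list(list(x = c(0, 1, 1, 0), y = c(0, 1, 0, 1))))
#' lay <- newPatchLayer(bow, 1L)       # invalid: crossing at (0.5, 0.5)
#' repairAndClip(lay)                  # two triangles, area 0.5
#' @export
repairAndClip <- function(layer, boundary = NULL) {
  stopifnot(is(layer, "PatchLayer"))
  if (!is.null(boundary)) {
    if (!is.null(boundary$x)) boundary <- list(boundary)
    boundary <- lapply(boundary, openRing)
    boundary <- tryCatch(
      polyclip::polysimplify(boundary, filltype = "evenodd",
                             eps = clipperEps(boundary)),
      error = function(e) stop("boundary invalid and unrepairable: ",
                               conditionMessage(e)))
    if (length(boundary) == 0 || abs(sum(vapply(boundary, ringArea,
                                                numeric(1)))) == 0)
      stop("boundary invalid and unrepairable: empty covered region")
  }
  keep <- logical(nPatches(layer))
  geoms <- vector("list", nPatches(layer))
  for (i in seq_len(nPatches(layer))) {
    g <- layer@geometry[[i]]
    if (!geomIsValid(g))
      g <- polyclip::polysimplify(g, filltype = "evenodd",
                                  eps = clipperEps(g))
    if (!is.null(boundary) && length(g))
      g <- polyclip::polyclip(g, boundary, op = "intersection",
                              fillA = "evenodd", fillB = "evenodd",
                              eps = clipperEps(g, boundary))
    a <- if (length(g)) sum(vapply(g, ringArea, numeric(1))) else 0
    if (a > 0) {
      keep[i] <- TRUE
      geoms[[i]] <- g
    }
  }
  newPatchLayer(geoms[keep], layer@patchId[keep], crs = layer@crs)
}
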