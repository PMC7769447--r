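#' @import methods
NULL

#' PatchLayer: identified habitat polygons with areas
#'
#' The central vector container of the package: one habitat patch per
#' element, each a simple polygon or multipolygon in a projected
#' (metric) coordinate system. Geometry is stored as a list of rings in
#' the \pkg{polyclip} convention: each ring is a \code{list(x, y)} of
#' open (unclosed) vertex sequences; rings with positive signed
#' (shoelace) area are exterior boundaries, rings with negative signed
#' area are holes. Areas are kept internally in square meters; reporting
#' functions convert to hectares (1 ha = 10,000 m2).
#'
#' @slot geometry list of patch geometries (each a list of rings).
#' @slot patchId integer vector of unique patch identifiers.
#' @slot area numeric vector of patch areas in m2 (derived from geometry).
#' @slot crs character scalar describing the coordinate reference system
#'   (free text; the package only verifies that coordinates are metric).
#' @seealso [readPatchLayer()], [repairAndClip()], [pairwiseEdgeDistances()]
#' @export
setClass("PatchLayer",
  representation(geometry = "list", patchId = "integer",
                 area = "numeric", crs = "character"),
  prototype(geometry = list(), patchId = integer(0),
            area = numeric(0), crs = NA_character_))

setValidity("PatchLayer", function(object) {
  n <- length(object@geometry)
  if (length(object@patchId) != n || length(object@area) != n)
    return("geometry, patchId and area must have equal length")
  if (anyDuplicated(object@patchId))
    return("duplicate patch id")
  if (n > 0 && any(!is.finite(object@area) | object@area <= 0))
    return("every patch area must be finite and > 0")
  ok <- vapply(object@geometry, function(g) {
    is.list(g) && length(g) > 0 &&
      all(vapply(g, function(r) {
        is.list(r) && length(r$x) == length(r$y) && length(r$x) >= 3 &&
          all(is.finite(r$x)) && all(is.finite(r$y))
      }, logical(1)))
  }, logical(1))
  if (n > 0 && !all(ok))
    return("each geometry must be a non-empty list of rings with >= 3 finite vertices")
  TRUE
})

#' EdgeList: pairwise edge-to-edge distances up to a cutoff
#'
#' Stores every unordered patch pair whose minimum boundary-to-boundary
#' Euclidean distance does not exceed \code{cutoff}. Touching or
#' overlapping patches have distance 0. This is the superset from which
#' all dispersal-threshold graphs are pruned.
#'
#' @slot from,to integer patch ids with \code{from < to} (pairs stored once).
#' @slot distance numeric distances in meters, all \code{<= cutoff}.
#' @slot cutoff numeric, the maximum distance retained (meters).
#' @seealso [pairwiseEdgeDistances()], [buildThresholdGraph()]
#' @export
setClass("EdgeList",
  representation(from = "integer", to = "integer",
                 distance = "numeric", cutoff = "numeric"),
  prototype(from = integer(0), to = integer(0),
            distance = numeric(0), cutoff = NA_real_))

setValidity("EdgeList", function(object) {
  m <- length(object@from)
  if (length(object@to) != m || length(object@distance) != m)
    return("from, to and distance must have equal length")
  if (m > 0) {
    if (any(object@from >= object@to))
      return("pairs must satisfy from < to (and no self-pairs)")
    if (anyDuplicated(cbind(object@from, object@to)))
      return("duplicate pair in edge list")
    if (any(object@distance < 0))
      return("distances must be >= 0")
    if (is.finite(object@cutoff) && any(object@distance > object@cutoff))
      return("all distances must be <= cutoff")
  }
  TRUE
})

#' ThresholdGraph: habitat graph at one dispersal distance
#'
#' Patches are nodes (with their areas as attributes); an undirected link
#' joins every pair whose edge-to-edge distance is at most the dispersal
#' distance threshold (inclusive comparison).
#'
#' @slot threshold numeric dispersal distance threshold in meters.
#' @slot nodeId integer patch ids.
#' @slot nodeArea numeric patch areas in m2 (parallel to \code{nodeId}).
#' @slot linkFrom,linkTo integer patch ids of the links (\code{from < to}).
#' @slot linkDist numeric link distances in meters, all \code{<= threshold}.
#' @seealso [buildThresholdGraph()], [iic()], [nodeImportance()]
#' @export
setClass("ThresholdGraph",
  representation(threshold = "numeric", nodeId = "integer",
                 nodeArea = "numeric", linkFrom = "integer",
                 linkTo = "integer", linkDist = "numeric"))

setValidity("ThresholdGraph", function(object) {
  if (length(object@nodeId) != length(object@nodeArea))
    return("nodeId and nodeArea must have equal length")
  if (anyDuplicated(object@nodeId)) return("duplicate node id")
  m <- length(object@linkFrom)
  if (length(object@linkTo) != m || length(object@linkDist) != m)
    return("link vectors must have equal length")
  if (m > 0) {
    if (any(object@linkFrom >= object@linkTo))
      return("links must satisfy from < to (no self-loops)")
    if (!all(c(object@linkFrom, object@linkTo) %in% object@nodeId))
      return("link references unknown node")
    if (any(object@linkDist > object@threshold))
      return("stored link distance exceeds threshold")
  }
  TRUE
})

#' ComponentPartition: connected components of a threshold graph
#'
#' A component is a maximal set of patches mutually reachable by links;
#' an isolated patch is itself a component. Component areas sum exactly
#' to the total habitat area.
#'
#' @slot nodeId integer patch ids.
#' @slot membership integer component index (1-based) per node.
#' @slot componentArea numeric total area (m2) per component index.
#' @slot threshold numeric, the threshold of the parent graph (meters).
#' @seealso [graphComponents()], [componentsCovering()]
#' @export
setClass("ComponentPartition",
  representation(nodeId = "integer", membership = "integer",
                 componentArea = "numeric", threshold = "numeric"))

setValidity("ComponentPartition", function(object) {
  if (length(object@nodeId) != length(object@membership))
    return("nodeId and membership must have equal length")
  k <- length(object@componentArea)
  if (length(object@membership) &&
      (min(object@membership) < 1L || max(object@membership) > k))
    return("membership index out of range")
  if (k > 0 && !all(seq_len(k) %in% object@membership))
    return("empty component index")
  TRUE
})

#' IICResult: the Integral Index of Connectivity at one threshold
#'
#' \code{iicNum} is the IIC numerator
#' \eqn{\sum_i \sum_j a_i a_j / (1 + nl_{ij})} in squared hectares, with
#' unreachable pairs contributing zero. The normalized index
#' \code{iic = iicNum / AL^2} is filled only when the total landscape
#' area \code{AL} (ha) is supplied.
#'
#' @slot threshold numeric, dispersal distance threshold (meters).
#' @slot iicNum numeric, IIC numerator (ha2).
#' @slot iic numeric in (0, 1], or NA when \code{AL} absent.
#' @slot AL numeric landscape area (ha), or NA.
#' @seealso [iic()]
#' @export
setClass("IICResult",
  representation(threshold = "numeric", iicNum = "numeric",
                 iic = "numeric", AL = "numeric"))

#' LandscapeConfig: parameters of the synthetic landscape generator
#'
#' Defaults emulate a mid-size central-European city's grassland mosaic:
#' about 2,000 strongly right-skewed patches (truncated lognormal sizes,
#' median 0.4 ha, range 0.003--1179 ha) in a 17 x 17 km extent with a
#' 200 m wide river-like barrier strip across the middle.
#'
#' @slot nPatches integer number of patches.
#' @slot extent numeric length-2 (width, height) of the extent in meters.
#' @slot medianHa,sigmaLog numeric lognormal size law: median (ha) and
#'   log-scale standard deviation.
#' @slot minHa,maxHa numeric truncation bounds of the size law (ha).
#' @slot minMappedHa numeric map resolution floor (ha); sizes below it are
#'   never generated (\code{minHa >= minMappedHa} is enforced).
#' @slot barrier list with elements \code{axis} ("horizontal" or
#'   "vertical"), \code{position} (strip center, m) and \code{width} (m),
#'   or an empty list for no barrier.
#' @slot clustering numeric in [0, 1]: probability that a patch is placed
#'   near an already-placed patch rather than uniformly.
#' @slot clusterSd numeric sd (m) of the clustered placement offset.
#' @slot seed integer random seed; every generator output is a pure
#'   function of the configuration including the seed.
#' @seealso [landscapeConfig()], [samplePatchSizes()], [placePatches()]
#' @export
setClass("LandscapeConfig",
  representation(nPatches = "integer", extent = "numeric",
                 medianHa = "numeric", sigmaLog = "numeric",
                 minHa = "numeric", maxHa = "numeric",
                 minMappedHa = "numeric", barrier = "list",
                 clustering = "numeric", clusterSd = "numeric",
                 seed = "integer"))

setValidity("LandscapeConfig", function(object) {
  if (object@nPatches < 1L) return("nPatches must be >= 1")
  if (length(object@extent) != 2L || any(object@extent <= 0))
    return("extent must be two positive lengths (meters)")
  if (object@minHa >= object@maxHa)
    return("infeasible truncation: minHa must be < maxHa")
  if (object@minHa < object@minMappedHa)
    return("minHa must be >= minMappedHa (map resolution floor)")
  if (object@sigmaLog <= 0) return("sigmaLog must be > 0")
  if (object@clustering < 0 || object@clustering > 1)
    return("clustering must be in [0, 1]")
  if (length(object@barrier) > 0) {
    b <- object@barrier
    if (!all(c("axis", "position", "width") %in% names(b)))
      return("barrier needs axis, position and width")
    if (!b$axis %in% c("horizontal", "vertical"))
      return("barrier axis must be 'horizontal' or 'vertical'")
    if (b$width <= 0) return("barrier width must be > 0")
  }
  TRUE
})

#' DistrictLayer: administrative districts with population counts
#'
#' Districts tile the analysis extent without overlap; populations are
#' non-negative. Used for green-space-per-capita analysis.
#'
#' @slot districtId integer district identifiers.
#' @slot geometry list of district geometries (list-of-rings, as in
#'   [PatchLayer-class]).
#' @slot population numeric population counts (>= 0).
#' @slot area numeric district areas in m2.
#' @seealso [generateDistricts()], [perCapita()]
#' @export
setClass("DistrictLayer",
  representation(districtId = "integer", geometry = "list",
                 population = "numeric", area = "numeric"))

setValidity("DistrictLayer", function(object) {
  n <- length(object@districtId)
  if (length(object@geometry) != n || length(object@population) != n ||
      length(object@area) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@districtId)) return("duplicate district id")
  if (n > 0 && any(object@population < 0))
    return("populations must be >= 0")
  TRUE
})

#' SweepReport: summary of a threshold sweep
#'
#' One row per dispersal distance threshold with the connectivity
#' descriptors NL (links), NC (components), the area-covering component
#' count, and the IIC numerator. Construction asserts the structural
#' monotonicity expected of nested threshold graphs: NL non-decreasing
#' and NC non-increasing down the (ascending) rows.
#'
#' @slot table data.frame with columns \code{threshold}, \code{NL},
#'   \code{NC}, \code{NCcovering}, \code{iicNum}, \code{iic}.
#' @slot provenance named list describing inputs, cutoff, coverage
#'   fraction, package version and seed.
#' @seealso [runSweep()]
#' @export
setClass("SweepReport",
  representation(table = "data.frame", provenance = "list"))

setValidity("SweepReport", function(object) {
  tab <- object@table
  need <- c("threshold", "NL", "NC", "NCcovering", "iicNum")
  if (!all(need %in% names(tab)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (is.unsorted(tab$threshold, strictly = TRUE))
    return("thresholds must be sorted ascending")
  if (nrow(tab) > 1) {
    if (any(diff(tab$NL) < 0))
      return("NL must be non-decreasing in threshold")
    if (any(diff(tab$NC) > 0))
      return("NC must be non-increasing in threshold")
  }
  TRUE
})
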