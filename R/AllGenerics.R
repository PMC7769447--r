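#' Accessors for patch and graph containers
#'
#' Small generic accessors used throughout: numbers of patches, patch
#' ids, areas (m2 or ha), link and component counts.
#'
#' @param x a [PatchLayer-class], [ThresholdGraph-class],
#'   [ComponentPartition-class] or [EdgeList-class] object.
#' @param unit `"m2"` or `"ha"` for area accessors.
#' @return `nPatches`: integer count. `patchIds`: integer vector.
#'   `patchAreas`: numeric vector. `numLinks`, `numComponents`: integer.
#' @examples
#' lay <- placePatches(c(1, 2), landscapeConfig(nPatches = 2, seed = 1))
#' nPatches(lay)
#' patchAreas(lay, unit = "ha")
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname accessors
#' @export
setGeneric("patchIds", function(x) standardGeneric("patchIds"))

#' @rdname accessors
#' @export
setGeneric("patchAreas", function(x, unit = c("m2", "ha"))
  standardGeneric("patchAreas"))

#' @rdname accessors
#' @export
setGeneric("numLinks", function(x) standardGeneric("numLinks"))

#' @rdname accessors
#' @export
setGeneric("numComponents", function(x) standardGeneric("numComponents"))

#' @rdname accessors
#' @export
setMethod("nPatches", "PatchLayer", function(x) length(x@patchId))

#' @rdname accessors
#' @export
setMethod("patchIds", "PatchLayer", function(x) x@patchId)

#' @rdname accessors
#' @export
setMethod("patchAreas", "PatchLayer", function(x, unit = c("m2", "ha")) {
  unit <- match.arg(unit)
  a <- stats::setNames(x@area, x@patchId)
  if (unit == "ha") a / 1e4 else a
})

#' @rdname accessors
#' @export
setMethod("nPatches", "ThresholdGraph", function(x) length(x@nodeId))

#' @rdname accessors
#' @export
setMethod("patchIds", "ThresholdGraph", function(x) x@nodeId)

#' @rdname accessors
#' @export
setMethod("patchAreas", "ThresholdGraph", function(x, unit = c("m2", "ha")) {
  unit <- match.arg(unit)
  a <- stats::setNames(x@nodeArea, x@nodeId)
  if (unit == "ha") a / 1e4 else a
})

#' @rdname accessors
#' @export
setMethod("numLinks", "ThresholdGraph", function(x) length(x@linkFrom))

#' @rdname accessors
#' @export
setMethod("numLinks", "EdgeList", function(x) length(x@from))

#' @rdname accessors
#' @export
setMethod("numComponents", "ComponentPartition",
          function(x) length(x@componentArea))

#' Edge table of an EdgeList
#'
#' @param x an [EdgeList-class].
#' @return data.frame with columns `from`, `to`, `distance` (meters).
#' @export
edgeTable <- function(x) {
  stopifnot(is(x, "EdgeList"))
  data.frame(from = x@from, to = x@to, distance = x@distance)
}

#' Component areas
#'
#' @param x a [ComponentPartition-class].
#' @param unit `"m2"` or `"ha"`.
#' @return numeric vector of component total areas, indexed by component.
#' @export
componentAreas <- function(x, unit = c("m2", "ha")) {
  stopifnot(is(x, "ComponentPartition"))
  unit <- match.arg(unit)
  if (unit == "ha") x@componentArea / 1e4 else x@componentArea
}

setMethod("show", "PatchLayer", function(object) {
  cat("PatchLayer with", length(object@patchId), "patches\n")
  if (length(object@area)) {
    ha <- object@area / 1e4
    cat(sprintf("  area [ha]: min %.4g, median %.4g, max %.4g, total %.6g\n",
                min(ha), stats::median(ha), max(ha), sum(ha)))
    bb <- layerBBox(object)
    cat(sprintf("  extent [m]: x %.6g..%.6g, y %.6g..%.6g\n",
                bb[1], bb[3], bb[2], bb[4]))
  }
  cat("  crs:", ifelse(is.na(object@crs), "<unspecified>", object@crs), "\n")
})

setMethod("show", "EdgeList", function(object) {
  cat("EdgeList:", length(object@from), "pairs within cutoff",
      object@cutoff, "m\n")
  if (length(object@distance))
    cat(sprintf("  distance [m]: min %.4g, median %.4g, max %.4g\n",
                min(object@distance), stats::median(object@distance),
                max(object@distance)))
})

setMethod("show", "ThresholdGraph", function(object) {
  cat("ThresholdGraph at d =", object@threshold, "m:",
      length(object@nodeId), "nodes,", length(object@linkFrom), "links\n")
})

setMethod("show", "ComponentPartition", function(object) {
  cat("ComponentPartition:", length(object@componentArea),
      "components over", length(object@nodeId), "nodes")
  if (is.finite(object@threshold))
    cat(" (d =", object@threshold, "m)")
  cat("\n")
})

setMethod("show", "IICResult", function(object) {
  cat(sprintf("IIC at d = %g m: numerator %.6g ha^2", object@threshold,
              object@iicNum))
  if (!is.na(object@iic))
    cat(sprintf(", IIC = %.6g (A_L = %.6g ha)", object@iic, object@AL))
  cat("\n")
})

setMethod("show", "LandscapeConfig", function(object) {
  cat("LandscapeConfig:", object@nPatches, "patches in",
      paste(object@extent, collapse = " x "), "m\n")
  cat(sprintf("  sizes: lognormal median %g ha, sigma %g, truncated [%g, %g] ha\n",
              object@medianHa, object@sigmaLog, object@minHa, object@maxHa))
  if (length(object@barrier))
    cat(sprintf("  barrier: %s strip at %g m, width %g m\n",
                object@barrier$axis, object@barrier$position,
                object@barrier$width))
  cat("  clustering:", object@clustering, " seed:", object@seed, "\n")
})

setMethod("show", "DistrictLayer", function(object) {
  cat("DistrictLayer with", length(object@districtId), "districts,",
      "total population", format(sum(object@population), big.mark = ","), "\n")
})

setMethod("show", "SweepReport", function(object) {
  cat("SweepReport over thresholds:",
      paste(object@table$threshold, collapse = ", "), "m\n")
  print(object@table, row.names = FALSE)
})

#' Report table of a threshold sweep
#'
#' @param x a [SweepReport-class].
#' @return the summary data.frame (one row per threshold).
#' @export
sweepTable <- function(x) {
  stopifnot(is(x, "SweepReport"))
  x@table
}
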