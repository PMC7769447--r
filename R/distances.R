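#' Pairwise edge-to-edge distances between patches
#'
#' Computes the minimum boundary-to-boundary Euclidean distance for
#' every unordered patch pair up to `cutoff` meters, returning an
#' [EdgeList-class]. Touching or overlapping patches get distance 0.
#' Candidate pairs are generated with a spatial grid index on bounding
#' boxes (cell size = cutoff), so far-apart pairs are never enumerated;
#' the exact segment-to-segment minimum is then evaluated in compiled
#' code. A brute-force all-pairs path (`method = "brute"`) is kept for
#' cross-checking on small layers.
#'
#' @param layer a [PatchLayer-class].
#' @param cutoff maximum distance retained, meters (> 0). Compute once
#'   with `cutoff = max(thresholds)`; every dispersal-threshold graph is
#'   then pruned from this superset.
#' @param method `"grid"` (spatial index, default) or `"brute"`.
#' @return an [EdgeList-class].
#' @examples
#' lay <- placePatches(c(1, 1, 2), landscapeConfig(nPatches = 3, seed = 4))
#' pairwiseEdgeDistances(lay, cutoff = 20000)
#' @export
pairwiseEdgeDistances <- function(layer, cutoff, method = c("grid", "brute")) {
  stopifnot(is(layer, "PatchLayer"))
  method <- match.arg(method)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0)
    stop("cutoff must be a single value > 0")
  n <- nPatches(layer)
  if (n < 2)
    return(new("EdgeList", from = integer(0), to = integer(0),
               distance = numeric(0), cutoff = cutoff))

  bb <- vapply(layer@geometry, geomBBox, numeric(4)) # 4 x n

  if (method == "brute") {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    ia <- idx[, 1]; ib <- idx[, 2]
  } else {
    cands <- gridCandidates(bb, cutoff)
    ia <- cands$ia; ib <- cands$ib
  }
  if (length(ia)) {
    # bounding-box separation prefilter (lower bound on true distance)
    gx <- pmax(0, pmax(bb[1, ia], bb[1, ib]) - pmin(bb[3, ia], bb[3, ib]))
    gy <- pmax(0, pmax(bb[2, ia], bb[2, ib]) - pmin(bb[4, ia], bb[4, ib]))
    ok <- gx * gx + gy * gy <= cutoff^2
    ia <- ia[ok]; ib <- ib[ok]
  }
  d <- if (length(ia)) cpp_pair_distances(layer@geometry, ia, ib) else numeric(0)
  keep <- d <= cutoff
  ia <- ia[keep]; ib <- ib[keep]; d <- d[keep]
  fromId <- layer@patchId[ia]; toId <- layer@patchId[ib]
  swap <- fromId > toId
  tmp <- fromId[swap]; fromId[swap] <- toId[swap]; toId[swap] <- tmp
  o <- order(fromId, toId)
  new("EdgeList", from = fromId[o], to = toId[o], distance = d[o],
      cutoff = cutoff)
}

# candidate pairs from a uniform grid over inflated bounding boxes
gridCandidates <- function(bb, cutoff) {
  n <- ncol(bb)
  cell <- cutoff
  half <- cutoff / 2
  cx1 <- floor((bb[1, ] - half) / cell)
  cx2 <- floor((bb[3, ] + half) / cell)
  cy1 <- floor((bb[2, ] - half) / cell)
  cy2 <- floor((bb[4, ] + half) / cell)
  ids <- integer(0); keys <- character(0)
  reps <- (cx2 - cx1 + 1) * (cy2 - cy1 + 1)
  ids <- rep.int(seq_len(n), reps)
  keys <- unlist(lapply(seq_len(n), function(i) {
    g <- expand.grid(x = cx1[i]:cx2[i], y = cy1[i]:cy2[i])
    paste(g$x, g$y)
  }), use.names = FALSE)
  pairs <- lapply(split(ids, keys), function(v) {
    if (length(v) < 2) return(NULL)
    v <- sort(v)
    k <- length(v)
    list(ia = rep(v[-k], times = (k - 1):1),
         ib = v[sequence((k - 1):1, from = rep(2:k, 1))])
  })
  ia <- unlist(lapply(pairs, `[[`, "ia"), use.names = FALSE)
  ib <- unlist(lapply(pairs, `[[`, "ib"), use.names = FALSE)
  if (is.null(ia)) return(list(ia = integer(0), ib = integer(0)))
  key <- ia * (n + 1) + ib
  keep <- !duplicated(key)
  list(ia = ia[keep], ib = ib[keep])
}
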