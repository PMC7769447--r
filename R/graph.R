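#' Build a dispersal-threshold graph
#'
#' Links every pair of patches whose edge-to-edge distance is at most
#' the dispersal distance threshold `d` (inclusive: a pair exactly at
#' the threshold is linked, since only links *exceeding* the threshold
#' are eliminated).
#'
#' @param nodes a [PatchLayer-class], or a data.frame with columns `id`
#'   and `area` (m2), e.g. as returned by [readConeforFiles()].
#' @param edges an [EdgeList-class] with `cutoff >= d`.
#' @param d dispersal distance threshold, meters.
#' @return a [ThresholdGraph-class].
#' @examples
#' nodes <- data.frame(id = 1:3, area = c(1e4, 1e4, 1e4))
#' ed <- new("EdgeList", from = c(1L, 2L, 1L), to = c(2L, 3L, 3L),
#'           distance = c(10, 10, 20), cutoff = 100)
#' numLinks(buildThresholdGraph(nodes, ed, d = 10))
#' @export
buildThresholdGraph <- function(nodes, edges, d) {
  stopifnot(is(edges, "EdgeList"))
  if (is(nodes, "PatchLayer")) {
    nodeId <- nodes@patchId
    nodeArea <- nodes@area
  } else {
    nodes <- as.data.frame(nodes)
    if (!all(c("id", "area") %in% names(nodes)))
      stop("nodes must be a PatchLayer or a data.frame with id and area")
    nodeId <- as.integer(nodes$id)
    nodeArea <- as.numeric(nodes$area)
  }
  if (!is.numeric(d) || length(d) != 1 || d < 0)
    stop("threshold d must be a single value >= 0")
  if (is.finite(edges@cutoff) && d > edges@cutoff)
    stop("threshold d = ", d, " exceeds the edge list cutoff ", edges@cutoff,
         "; the edge list is incomplete for this threshold")
  keep <- edges@distance <= d
  new("ThresholdGraph", threshold = d, nodeId = nodeId, nodeArea = nodeArea,
      linkFrom = edges@from[keep], linkTo = edges@to[keep],
      linkDist = edges@distance[keep])
}

# 1-based node indices of the links (m x 2 matrix)
linkIndexMatrix <- function(g) {
  idx <- match(c(g@linkFrom, g@linkTo), g@nodeId)
  matrix(idx, ncol = 2)
}

#' Connected components of a threshold graph
#'
#' A component is a maximal group of patches mutually reachable through
#' links; an isolated patch is a singleton component. Component indices
#' follow \pkg{igraph}'s deterministic labelling (order of first
#' appearance).
#'
#' @param g a [ThresholdGraph-class].
#' @return a [ComponentPartition-class]; component areas (m2) sum
#'   exactly to the total habitat area.
#' @export
graphComponents <- function(g) {
  stopifnot(is(g, "ThresholdGraph"))
  n <- length(g@nodeId)
  ig <- igraph::graph_from_edgelist(linkIndexMatrix(g), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  memb <- as.integer(igraph::components(ig)$membership)
  areas <- vapply(split(g@nodeArea, memb), sum, numeric(1))
  new("ComponentPartition", nodeId = g@nodeId, membership = memb,
      componentArea = as.numeric(areas), threshold = g@threshold)
}

#' Area-covering component count
#'
#' The smallest number of largest components whose summed area strictly
#' exceeds a fraction `p` of the total habitat area. At `p = 0.5` this
#' is the "number of components covering more than half the habitat", a
#' refinement of NC for strongly right-skewed patch-size distributions
#' where a handful of components can hold most of the area.
#'
#' @param partition a [ComponentPartition-class].
#' @param p coverage fraction in (0, 1].
#' @return integer count; ties in component area are broken by lower
#'   component index, and if no strict exceedance is possible (`p = 1`)
#'   the total number of components is returned.
#' @examples
#' g <- buildThresholdGraph(data.frame(id = 1:3, area = c(60, 25, 15)),
#'        new("EdgeList", cutoff = 10), d = 5)
#' componentsCovering(graphComponents(g), p = 0.5)  # 1: 60 > 50
#' @export
componentsCovering <- function(partition, p = 0.5) {
  stopifnot(is(partition, "ComponentPartition"))
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 1)
    stop("p must be a single fraction in (0, 1]")
  areas <- partition@componentArea
  if (length(areas) == 0) return(0L)
  o <- order(-areas, seq_along(areas))  # ties: lower component index first
  cum <- cumsum(areas[o])
  k <- which(cum > p * sum(areas))
  if (length(k) == 0) length(areas) else as.integer(k[1])
}

#' All-pairs topological shortest-path link counts
#'
#' For every ordered pair of patches in the same component, the minimum
#' number of links on a path between them (`nl`), computed by
#' breadth-first search from every node, per component. Pairs in
#' different components are unreachable and are *absent* from the sparse
#' result (never encoded as a large number).
#'
#' @param g a [ThresholdGraph-class].
#' @param dense if `TRUE`, additionally return the full symmetric matrix
#'   with `Inf` marking unreachable pairs (only sensible for small
#'   graphs).
#' @return data.frame with columns `from`, `to` (patch ids, `from < to`)
#'   and `nl`; with `dense = TRUE`, a list `list(pairs, matrix)`.
#' @examples
#' nodes <- data.frame(id = 1:3, area = rep(1, 3))
#' ed <- new("EdgeList", from = c(1L, 2L), to = c(2L, 3L),
#'           distance = c(1, 1), cutoff = 10)
#' allPairsLinkCounts(buildThresholdGraph(nodes, ed, d = 10))
#' @export
allPairsLinkCounts <- function(g, dense = FALSE) {
  stopifnot(is(g, "ThresholdGraph"))
  n <- length(g@nodeId)
  res <- cpp_all_pairs_nl(n, linkIndexMatrix(g))
  pairs <- data.frame(from = g@nodeId[res$from], to = g@nodeId[res$to],
                      nl = res$nl)
  swap <- pairs$from > pairs$to
  tmp <- pairs$from[swap]; pairs$from[swap] <- pairs$to[swap]
  pairs$to[swap] <- tmp
  if (!dense) return(pairs)
  m <- matrix(Inf, n, n, dimnames = list(g@nodeId, g@nodeId))
  diag(m) <- 0
  i <- match(pairs$from, g@nodeId); j <- match(pairs$to, g@nodeId)
  m[cbind(i, j)] <- pairs$nl
  m[cbind(j, i)] <- pairs$nl
  list(pairs = pairs, matrix = m)
}
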