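# Independent oracles, kept deliberately naive: Floyd-Warshall link
# counts, exhaustive pair enumeration for the IIC numerator, and
# remove-and-recompute node importance.

# all-pairs link counts by Floyd-Warshall on unit weights; Inf = unreachable
fwLinkCounts <- function(n, from, to) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (e in seq_along(from)) {
    d[from[e], to[e]] <- 1
    d[to[e], from[e]] <- 1
  }
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

# IIC numerator by exhaustive enumeration of ordered pairs (incl. i == j)
oracleIICnum <- function(areas, nlMat) {
  terms <- outer(areas, areas) / (1 + nlMat)
  sum(terms[is.finite(nlMat)])
}

# dIIC (percent) of node k by removal and full recomputation
oracleDIIC <- function(areas, from, to, k) {
  n <- length(areas)
  full <- oracleIICnum(areas, fwLinkCounts(n, from, to))
  keep <- from != k & to != k
  sub <- setdiff(seq_len(n), k)
  d2 <- fwLinkCounts(n - 1, match(from[keep], sub), match(to[keep], sub))
  reduced <- oracleIICnum(areas[sub], d2)
  100 * (full - reduced) / full
}

# random graph as (nodes, EdgeList) with unit link distances; areas in m2
randomGraph <- function(n, pEdge, seed) {
  set.seed(seed)
  areas <- stats::runif(n, 0.05, 8) * 1e4
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < pEdge
  nodes <- data.frame(id = seq_len(n), area = areas)
  edges <- new("EdgeList", from = as.integer(pairs[keep, 1]),
               to = as.integer(pairs[keep, 2]),
               distance = rep(1, sum(keep)), cutoff = 10)
  list(nodes = nodes, edges = edges,
       graph = buildThresholdGraph(nodes, edges, d = 5))
}

# a small layer of random disjoint axis-aligned squares (areas in ha)
randomSquareLayer <- function(n, seed, extent = 2000) {
  cfg <- landscapeConfig(nPatches = n, extent = c(extent, extent),
                         medianHa = 0.2, sigmaLog = 1, minHa = 0.01,
                         maxHa = 3, minMappedHa = 0.01, barrier = NULL,
                         seed = seed)
  placePatches(samplePatchSizes(cfg), cfg)
}
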