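triangleNodes <- data.frame(id = 1:3, area = rep(1e4, 3))
triangleEdges <- new("EdgeList", from = c(1L, 2L, 1L), to = c(2L, 3L, 3L),
                     distance = c(10, 10, 20), cutoff = 100)

test_that("threshold pruning is inclusive and errors beyond the cutoff", {
  g10 <- buildThresholdGraph(triangleNodes, triangleEdges, d = 10)
  expect_equal(numLinks(g10), 2L)
  expect_setequal(paste(g10@linkFrom, g10@linkTo), c("1 2", "2 3"))
  expect_equal(numLinks(buildThresholdGraph(triangleNodes, triangleEdges, 5)),
               0L)
  # boundary case: distance exactly at d stays linked
  expect_equal(numLinks(buildThresholdGraph(triangleNodes, triangleEdges, 20)),
               3L)
  expect_error(buildThresholdGraph(triangleNodes, triangleEdges, d = 500),
               "incomplete")
})

test_that("components partition nodes and conserve area", {
  g0 <- buildThresholdGraph(triangleNodes, triangleEdges, d = 5)
  expect_equal(numComponents(graphComponents(g0)), 3L)

  path <- buildThresholdGraph(triangleNodes, triangleEdges, d = 10)
  expect_equal(numComponents(graphComponents(path)), 1L)

  nodes5 <- data.frame(id = 1:5, area = c(10, 20, 30, 40, 50))
  ed5 <- new("EdgeList", from = c(1L, 4L), to = c(2L, 5L),
             distance = c(1, 1), cutoff = 10)
  part <- graphComponents(buildThresholdGraph(nodes5, ed5, 5))
  expect_equal(numComponents(part), 3L)
  expect_setequal(componentAreas(part), c(30, 30, 90))
  expect_equal(sum(componentAreas(part)), sum(nodes5$area))
})

test_that("area-covering component count uses strict exceedance", {
  mkPart <- function(areas) {
    n <- length(areas)
    new("ComponentPartition", nodeId = seq_len(n), membership = seq_len(n),
        componentArea = areas, threshold = 1)
  }
  expect_equal(componentsCovering(mkPart(c(60, 25, 15)), 0.5), 1L)
  expect_equal(componentsCovering(mkPart(c(40, 30, 20, 10)), 0.5), 2L)
  expect_equal(componentsCovering(mkPart(c(50, 50)), 0.5), 2L)
  expect_equal(componentsCovering(mkPart(c(10, 10)), 1), 2L)
  expect_error(componentsCovering(mkPart(c(1, 2)), 0), "fraction")
})

test_that("all-pairs link counts match trivial paths and mark unreachable", {
  path <- buildThresholdGraph(triangleNodes, triangleEdges, d = 10)
  res <- allPairsLinkCounts(path, dense = TRUE)
  expect_equal(res$matrix["1", "3"], 2)
  expect_equal(res$matrix["1", "2"], 1)
  expect_equal(unname(diag(res$matrix)), c(0, 0, 0))

  iso <- buildThresholdGraph(data.frame(id = 1:2, area = c(1, 1)),
                             new("EdgeList", cutoff = 10), d = 5)
  m <- allPairsLinkCounts(iso, dense = TRUE)
  expect_equal(nrow(m$pairs), 0L)
  expect_identical(m$matrix["1", "2"], Inf)
})

test_that("BFS link counts equal Floyd-Warshall on random graphs", {
  for (seed in 1:5) {
    rg <- randomGraph(30, pEdge = 0.08, seed = seed)
    dense <- allPairsLinkCounts(rg$graph, dense = TRUE)$matrix
    fw <- fwLinkCounts(30, rg$edges@from, rg$edges@to)
    dimnames(fw) <- dimnames(dense)
    expect_equal(dense, fw)
    # independent second route: igraph unweighted distances
    ig <- igraph::graph_from_edgelist(cbind(rg$edges@from, rg$edges@to),
                                      directed = FALSE)
    ig <- igraph::add_vertices(ig, 30 - igraph::vcount(ig))
    expect_equal(unname(dense), unname(igraph::distances(ig)))
  }
})

test_that("NL grows and NC shrinks with the dispersal threshold", {
  lay <- randomSquareLayer(150, seed = 3, extent = 3000)
  ed <- pairwiseEdgeDistances(lay, cutoff = 1000)
  thresholds <- c(2, 20, 44, 100, 1000)
  nl <- nc <- ncov <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    g <- buildThresholdGraph(lay, ed, thresholds[i])
    part <- graphComponents(g)
    nl[i] <- numLinks(g)
    nc[i] <- numComponents(part)
    ncov[i] <- componentsCovering(part, 0.5)
    expect_equal(sum(componentAreas(part)), sum(lay@area))
  }
  expect_true(all(diff(nl) >= 0))
  expect_true(all(diff(nc) <= 0))
  expect_true(all(ncov <= nc))
  # coarser partitions cover the target fraction with fewer components
  expect_true(all(diff(ncov) <= 0))
})
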