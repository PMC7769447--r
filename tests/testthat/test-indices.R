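pathGraph3 <- function(areaHa = 1) {
  nodes <- data.frame(id = 1:3, area = rep(areaHa * 1e4, 3))
  ed <- new("EdgeList", from = c(1L, 2L), to = c(2L, 3L),
            distance = c(1, 1), cutoff = 10)
  buildThresholdGraph(nodes, ed, d = 5)
}

test_that("IIC matches hand-enumerated closed forms", {
  # single patch covering the whole landscape
  single <- buildThresholdGraph(data.frame(id = 1L, area = 2e4),
                                new("EdgeList", cutoff = 10), d = 5)
  r1 <- iic(single, AL = 2)
  expect_equal(r1@iicNum, 4)
  expect_equal(r1@iic, 1)

  # two isolated unit patches: unreachable pairs contribute zero
  iso <- buildThresholdGraph(data.frame(id = 1:2, area = c(1e4, 1e4)),
                             new("EdgeList", cutoff = 10), d = 5)
  r2 <- iic(iso, AL = 2)
  expect_equal(r2@iicNum, 2)
  expect_equal(r2@iic, 0.5)

  # path 1-2-3 with unit areas: 3 + 2/2 + 2/2 + 2/3 = 17/3
  expect_equal(iic(pathGraph3())@iicNum, 17 / 3, tolerance = 1e-12)
  # areas scale the numerator quadratically
  expect_equal(iic(pathGraph3(areaHa = 2.5))@iicNum, 2.5^2 * 17 / 3,
               tolerance = 1e-12)

  expect_error(iic(pathGraph3(), AL = -1), "AL")
  expect_warning(iic(pathGraph3(), AL = 1), "exceeds")
})

test_that("node importance reproduces the hand-derived path example", {
  imp <- nodeImportance(pathGraph3())
  mid <- imp[imp$patchId == 2, ]
  expect_equal(mid$dIIC, 1100 / 17, tolerance = 1e-12)
  expect_equal(mid$dIICintra, 300 / 17, tolerance = 1e-12)
  expect_equal(mid$dIICflux, 600 / 17, tolerance = 1e-12)
  expect_equal(mid$dIICconnector, 200 / 17, tolerance = 1e-12)
  # leaves are no stepping stones
  expect_equal(imp$dIICconnector[imp$patchId != 2], c(0, 0))
  expect_equal(mid$rank, 1L)
  expect_equal(mid$normalizedRank, 1)
  expect_error(nodeImportance(
    buildThresholdGraph(data.frame(id = 1L, area = 1),
                        new("EdgeList", cutoff = 1), d = 1)),
    "single-patch")
})

test_that("isolated patches have dIIC equal to their intra fraction", {
  nodes <- data.frame(id = 1:3, area = c(1e4, 3e4, 2e4))
  ed <- new("EdgeList", from = 1L, to = 2L, distance = c(1), cutoff = 10)
  imp <- nodeImportance(buildThresholdGraph(nodes, ed, d = 5))
  isoRow <- imp[imp$patchId == 3, ]
  expect_equal(isoRow$dIICflux, 0)
  expect_equal(isoRow$dIICconnector, 0)
  expect_equal(isoRow$dIIC, isoRow$dIICintra)
})

test_that("partition identity and removal oracle hold on random graphs", {
  # the acceptance suite runs the full 100-graph version; this is a
  # fast regression at smaller n with both sparse and dense topologies
  for (seed in 1:10) {
    rg <- randomGraph(n = 20 + (seed %% 3) * 10,
                      pEdge = c(0.05, 0.15, 0.5)[1 + seed %% 3], seed = seed)
    imp <- nodeImportance(rg$graph)
    expect_equal(imp$dIIC,
                 imp$dIICintra + imp$dIICflux + imp$dIICconnector,
                 tolerance = 1e-12)
    areasHa <- rg$nodes$area / 1e4
    for (k in sample(nrow(rg$nodes), 5)) {
      expect_equal(imp$dIIC[k],
                   oracleDIIC(areasHa, rg$edges@from, rg$edges@to, k),
                   tolerance = 1e-9)
    }
  }
})

test_that("dIIC and fractions are invariant to the landscape area", {
  rg <- randomGraph(25, 0.1, seed = 99)
  expect_equal(nodeImportance(rg$graph), nodeImportance(rg$graph))
  r1 <- iic(rg$graph, AL = 1e3)
  r2 <- iic(rg$graph, AL = 2e3)
  expect_equal(r1@iicNum, r2@iicNum)
  expect_equal(r1@iic / r2@iic, (2e3 / 1e3)^2, tolerance = 1e-12)
})

test_that("closed-form bounds: edgeless and fully connected graphs", {
  set.seed(5)
  n <- 12
  areas <- runif(n, 0.2, 4) * 1e4
  aHa <- areas / 1e4
  nodes <- data.frame(id = seq_len(n), area = areas)
  empty <- buildThresholdGraph(nodes, new("EdgeList", cutoff = 10), d = 5)
  expect_equal(iic(empty)@iicNum, sum(aHa^2), tolerance = 1e-12)

  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  full <- buildThresholdGraph(nodes,
    new("EdgeList", from = as.integer(pairs[, 1]),
        to = as.integer(pairs[, 2]),
        distance = rep(1, nrow(pairs)), cutoff = 10), d = 5)
  expect_equal(iic(full)@iicNum,
               sum(aHa^2) + sum(outer(aHa, aHa)[upper.tri(diag(n))]),
               tolerance = 1e-12)
})

test_that("the IIC numerator is non-decreasing in the threshold", {
  lay <- randomSquareLayer(80, seed = 21, extent = 2500)
  ed <- pairwiseEdgeDistances(lay, cutoff = 1000)
  vals <- vapply(c(2, 20, 44, 100, 1000), function(d)
    iic(buildThresholdGraph(lay, ed, d))@iicNum, numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("fraction shares sum to 100 and follow hand-derived cases", {
  # path middle node: shares proportional to (300, 600, 200)/1100
  imp <- nodeImportance(pathGraph3())
  fp <- fractionProfile(imp)
  expect_equal(fp$intraShare + fp$fluxShare + fp$connectorShare, 100,
               tolerance = 1e-9)
  midShares <- 100 * c(300, 600, 200) / 1100
  ends <- 100 * c(300 / 800, 500 / 800, 0)
  expect_equal(c(fp$intraShare, fp$fluxShare, fp$connectorShare),
               (midShares + 2 * ends) / 3, tolerance = 1e-9)

  # no links: dIIC is pure patch size
  iso <- buildThresholdGraph(data.frame(id = 1:4, area = c(1:4) * 1e4),
                             new("EdgeList", cutoff = 10), d = 5)
  fpIso <- fractionProfile(nodeImportance(iso))
  expect_equal(c(fpIso$intraShare, fpIso$fluxShare, fpIso$connectorShare),
               c(100, 0, 0))

  # two connected equal patches: intra = a^2, flux = 2 a^2 / 2 = a^2
  duo <- buildThresholdGraph(data.frame(id = 1:2, area = c(1e4, 1e4)),
    new("EdgeList", from = 1L, to = 2L, distance = 1, cutoff = 10), d = 5)
  fpDuo <- fractionProfile(nodeImportance(duo))
  expect_equal(c(fpDuo$intraShare, fpDuo$fluxShare, fpDuo$connectorShare),
               c(50, 50, 0), tolerance = 1e-12)
})
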