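test_that("patch sizes follow the truncated lognormal law deterministically", {
  cfg <- landscapeConfig(nPatches = 2000L, seed = 42)
  sizes <- samplePatchSizes(cfg)
  expect_length(sizes, 2000L)
  expect_true(all(sizes >= cfg@minHa & sizes <= cfg@maxHa))
  expect_identical(sizes, samplePatchSizes(cfg))

  # closed-form check: the median of the truncated law is
  # qlnorm((F(lo) + F(hi))/2), about 0.41 ha for the default law
  mlog <- log(cfg@medianHa)
  trueMedian <- qlnorm((plnorm(cfg@minHa, mlog, cfg@sigmaLog) +
                        plnorm(cfg@maxHa, mlog, cfg@sigmaLog)) / 2,
                       mlog, cfg@sigmaLog)
  expect_gt(trueMedian, 0.3); expect_lt(trueMedian, 0.5)
  expect_equal(median(sizes), trueMedian, tolerance = 0.2)
  expect_gt(median(sizes), 0.3); expect_lt(median(sizes), 0.5)

  # raised lower truncation bound is respected
  cfgHi <- landscapeConfig(minHa = 0.1, minMappedHa = 0.1, seed = 1)
  expect_gte(min(samplePatchSizes(cfgHi)), 0.1)
  expect_error(landscapeConfig(minHa = 5, maxHa = 2), "truncation")
})

test_that("the default size law is dominated by sub-0.5 ha patches", {
  sizes <- samplePatchSizes(landscapeConfig(seed = 1))
  # doubling (semi-logarithmic) area classes as in patch-size histograms
  breaks <- c(0, 0.5, 1, 2, 4, 8, 16, 32, 64, 128, Inf)
  counts <- as.integer(table(cut(sizes, breaks)))
  # the sub-0.5 ha class dominates (most numerous, > 40% of patches)
  expect_equal(which.max(counts), 1L)
  expect_gt(counts[1], 0.4 * length(sizes))
  # and the right tail of the distribution falls off class by class
  expect_true(all(diff(counts[-(1:2)]) <= 0))
  # while a few large patches still hold a sizeable share of total area
  expect_gt(sum(sizes[sizes > 100]) / sum(sizes), 0.25)
})

test_that("patches are placed disjointly, away from the barrier, reproducibly", {
  cfg <- landscapeConfig(nPatches = 300L, extent = c(8000, 8000),
                         maxHa = 30, seed = 9)
  lay <- placePatches(samplePatchSizes(cfg), cfg)
  expect_equal(nPatches(lay), 300L)
  expect_s4_class(lay, "PatchLayer")

  bb <- vapply(lay@geometry, patchConnect:::geomBBox, numeric(4))
  # pairwise disjoint (strict interior overlap forbidden)
  ed0 <- pairwiseEdgeDistances(lay, cutoff = 1)
  ov <- edgeTable(ed0)
  expect_true(all(ov$distance > 0 | ov$distance == 0)) # distances defined
  for (r in seq_len(nrow(ov))) {
    i <- ov$from[r]; j <- ov$to[r]
    interW <- min(bb[3, i], bb[3, j]) - max(bb[1, i], bb[1, j])
    interH <- min(bb[4, i], bb[4, j]) - max(bb[2, i], bb[2, j])
    expect_lte(min(interW, interH), 1e-9)
  }
  # no patch inside the barrier strip (y in position +/- width/2)
  strip <- cfg@barrier$position + c(-1, 1) * cfg@barrier$width / 2
  expect_true(all(bb[4, ] <= strip[1] | bb[2, ] >= strip[2]))

  expect_identical(placePatches(samplePatchSizes(cfg), cfg)@geometry,
                   lay@geometry)
  # over-filled extents fail loudly rather than overlapping silently
  tiny <- landscapeConfig(nPatches = 40L, extent = c(300, 300),
                          medianHa = 1, minHa = 0.5, maxHa = 3,
                          minMappedHa = 0.5, barrier = NULL, seed = 2)
  expect_error(placePatches(samplePatchSizes(tiny), tiny), "placement")
})

test_that("patch layers on both banks sit at least a barrier width apart", {
  cfg <- landscapeConfig(nPatches = 60L, extent = c(4000, 4000),
                         maxHa = 5, seed = 5,
                         barrier = list(axis = "horizontal",
                                        position = 2000, width = 300))
  lay <- placePatches(samplePatchSizes(cfg), cfg)
  bb <- vapply(lay@geometry, patchConnect:::geomBBox, numeric(4))
  north <- bb[2, ] >= 2150
  expect_true(any(north) && any(!north))
  ed <- pairwiseEdgeDistances(lay, cutoff = 4000)
  tab <- edgeTable(ed)
  cross <- north[tab$from] != north[tab$to]
  expect_true(all(tab$distance[cross] >= 300))
})

test_that("synthetic GeoJSON output is byte-identical across reruns", {
  cfg <- landscapeConfig(nPatches = 40L, extent = c(3000, 3000),
                         maxHa = 5, seed = 7)
  f1 <- tempfile(fileext = ".geojson"); f2 <- tempfile(fileext = ".geojson")
  writePatchLayer(placePatches(samplePatchSizes(cfg), cfg), f1)
  writePatchLayer(placePatches(samplePatchSizes(cfg), cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("clustered placement pulls patches closer together", {
  base <- landscapeConfig(nPatches = 150L, extent = c(10000, 10000),
                          maxHa = 2, barrier = NULL, seed = 11)
  clus <- landscapeConfig(nPatches = 150L, extent = c(10000, 10000),
                          maxHa = 2, barrier = NULL, seed = 11,
                          clustering = 0.9, clusterSd = 200)
  layU <- placePatches(samplePatchSizes(base), base)
  layC <- placePatches(samplePatchSizes(clus), clus)
  nnDist <- function(lay) {
    ce <- vapply(lay@geometry, patchConnect:::geomCentroid, numeric(2))
    d <- as.matrix(dist(t(ce))); diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  expect_lt(nnDist(layC), nnDist(layU))
})

test_that("districts tile the extent with a center-peaked density gradient", {
  cfg <- landscapeConfig(extent = c(9000, 9000), seed = 1)
  dl <- generateDistricts(cfg, nDistricts = 9)
  expect_s4_class(dl, "DistrictLayer")
  expect_equal(length(dl@districtId), 9L)
  expect_equal(sum(dl@area), 9000 * 9000, tolerance = 1e-9)

  dens <- dl@population / (dl@area / 1e6)
  # central district (3x3 grid -> index 5) has the maximum population
  expect_equal(which.max(dl@population), 5L)
  expect_true(all(dens >= 83.1 * 0.99 & dens <= 14025 * 1.01))
  expect_identical(generateDistricts(cfg, 9)@population, dl@population)
  expect_error(generateDistricts(cfg, 1), "nDistricts")
})
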