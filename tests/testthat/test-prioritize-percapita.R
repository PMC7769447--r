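fakeImportance <- function(dIIC, area = NULL, threshold = 44) {
  n <- length(dIIC)
  area <- area %||% rev(seq_len(n))
  rk <- integer(n)
  rk[order(-dIIC, -area, seq_len(n))] <- seq_len(n)
  out <- data.frame(patchId = seq_len(n), areaHa = area, dIIC = dIIC,
                    dIICintra = dIIC * 0.6, dIICflux = dIIC * 0.3,
                    dIICconnector = dIIC * 0.1, rank = rk,
                    normalizedRank = dIIC / max(dIIC))
  attr(out, "threshold") <- threshold
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("top-fraction selection uses the ceiling and the rank tie-break", {
  imp <- fakeImportance(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))
  expect_setequal(topFraction(imp, 0.2), c(1L, 2L))
  expect_setequal(topFraction(imp, 0.25), c(1L, 2L, 3L))  # ceil(2.5) = 3
  expect_setequal(topFraction(imp, 1), 1:10)
  expect_error(topFraction(imp, 0), "fraction")

  tied <- fakeImportance(rep(5, 4), area = c(1, 4, 2, 3))
  expect_setequal(topFraction(tied, 0.5), c(2L, 4L))  # larger area wins
})

test_that("Spearman matrix detects monotone relations and masks by p-value", {
  n <- 60
  area <- sort(runif(n, 0.1, 50))
  imp <- fakeImportance(dIIC = area^2 / 10, area = area)  # monotone in area
  cm <- correlationMatrix(imp)
  expect_equal(cm$rho["area", "dIIC"], 1)
  expect_equal(cm$rho["dIIC", "intra"], 1)
  expect_true(isSymmetric(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 5))

  rev <- fakeImportance(dIIC = max(area) + 1 - area, area = area)
  expect_equal(correlationMatrix(rev)$rho["area", "dIIC"], -1)

  const <- fakeImportance(dIIC = rep(3, 10), area = 1:10)
  cmc <- correlationMatrix(const)
  expect_true("dIIC" %in% cmc$dropped)
  expect_true(is.na(cmc$rho["area", "dIIC"]))
  expect_error(correlationMatrix(fakeImportance(1:3)), "at least 5")
})

test_that("independent variables are rarely flagged significant", {
  # permutation null: uncorrelated area and dIIC should give small rho
  # with p > 0.05 in the vast majority of draws
  hits <- 0
  for (seed in 1:40) {
    set.seed(seed)
    imp <- fakeImportance(dIIC = sample(200), area = runif(200))
    cm <- correlationMatrix(imp, mask = TRUE)
    expect_lt(abs(cm$rho["area", "dIIC"]), 0.2)
    if (!is.na(cm$masked["area", "dIIC"])) hits <- hits + 1
  }
  expect_lte(hits, 6)  # ~5% expected at alpha = 0.05
})

test_that("our Spearman agrees with brute-force rank-then-Pearson", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- sample(50, replace = TRUE); y <- rnorm(50)  # ties included
    imp <- fakeImportance(dIIC = y - min(y) + 0.1, area = x)
    cm <- correlationMatrix(imp)
    expect_equal(cm$rho["area", "dIIC"], cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
})

test_that("per-capita areas follow exact intersection and division", {
  # one district, 1300 m2 of grassland, 100 people -> 13 m2 per person
  districts <- new("DistrictLayer", districtId = 1L,
                   geometry = list(list(rectRing(0, 0, 1000, 1000))),
                   population = 100, area = 1e6)
  patches <- newPatchLayer(list(list(rectRing(10, 10, 36, 60))), 1L,
                           crs = "m")  # 26 x 50 = 1300 m2
  pc <- perCapita(patches, districts)
  expect_equal(pc$grasslandM2, 1300)
  expect_equal(pc$areaPerCapita, 13)
  expect_equal(pc$densityKm2, 100)

  # patch straddling two equal districts is split half and half
  districts2 <- new("DistrictLayer", districtId = 1:2,
                    geometry = list(list(rectRing(0, 0, 500, 1000)),
                                    list(rectRing(500, 0, 1000, 1000))),
                    population = c(10, 40), area = c(5e5, 5e5))
  straddle <- newPatchLayer(list(list(rectRing(400, 400, 600, 500))), 1L,
                            crs = "m")
  pc2 <- perCapita(straddle, districts2)
  expect_equal(pc2$grasslandM2, c(1e4, 1e4))
  expect_equal(pc2$areaPerCapita, c(1000, 250))
  expect_equal(sum(pc2$grasslandM2), sum(patchAreas(straddle)),
               tolerance = 1e-9)

  # zero population: flagged undefined, excluded from the relation
  districts2@population <- c(0, 40)
  pc3 <- perCapita(straddle, districts2)
  expect_true(is.na(pc3$areaPerCapita[1]))
})

test_that("district grassland areas are additive over the synthetic mosaic", {
  cfg <- landscapeConfig(nPatches = 120L, extent = c(6000, 6000),
                         maxHa = 20, seed = 13)
  land <- synthesizeLandscape(cfg, nDistricts = 9)
  pc <- perCapita(land$patches, land$districts)
  expect_equal(sum(pc$grasslandM2), sum(land$patches@area),
               tolerance = 1e-6)
})

test_that("center-peaked districts show a negative density/per-capita relation", {
  cfg <- landscapeConfig(nPatches = 250L, extent = c(10000, 10000),
                         maxHa = 20, barrier = NULL, seed = 17)
  land <- synthesizeLandscape(cfg, nDistricts = 25)
  pc <- perCapita(land$patches, land$districts)
  rel <- logLogRelation(pc)
  expect_lt(rel$rho, 0)
  expect_lt(rel$slope, 0)
  expect_equal(rel$n, sum(pc$grasslandM2 > 0 & pc$population > 0))
})
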