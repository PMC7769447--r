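#' Configure a synthetic patch landscape
#'
#' Builds a [LandscapeConfig-class] describing a synthetic habitat
#' mosaic. The defaults emulate the grassland mosaic of a mid-size
#' central-European city: ~2,000 patches with a strongly right-skewed
#' (truncated lognormal) size distribution - median 0.4 ha, extremes
#' 0.003 and 1179 ha, most patches below 0.5 ha while a handful of very
#' large patches hold much of the total area - spread over a 17 x 17 km
#' extent (habitat fraction roughly a quarter to a third of the city
#' area), with a 200 m wide river-like barrier strip crossing the
#' middle and splitting the mosaic into two banks.
#'
#' @param nPatches number of patches (default 2000).
#' @param extent numeric length-2, width and height of the extent in
#'   meters (default `c(17000, 17000)`).
#' @param medianHa median patch size in hectares (default 0.4).
#' @param sigmaLog lognormal log-scale sd (default 2.1; heavy right tail).
#' @param minHa,maxHa truncation bounds in hectares (defaults 0.003 and
#'   1179).
#' @param minMappedHa map resolution floor in ha (default 0.003; sizes
#'   below it cannot occur).
#' @param barrier list(axis, position, width) in meters, `NULL`/empty
#'   list for none. Default: horizontal strip of width 200 m across the
#'   extent center.
#' @param clustering probability in \[0, 1\] of clustered (near an
#'   existing patch) rather than uniform placement (default 0).
#' @param clusterSd sd of the clustered placement offset, meters.
#' @param seed integer random seed.
#' @return a validated [LandscapeConfig-class].
#' @seealso [samplePatchSizes()], [placePatches()], [generateDistricts()],
#'   [synthesizeLandscape()]
#' @export
landscapeConfig <- function(nPatches = 2000L, extent = c(17000, 17000),
                            medianHa = 0.4, sigmaLog = 2.1,
                            minHa = 0.003, maxHa = 1179,
                            minMappedHa = 0.003,
                            barrier = list(axis = "horizontal",
                                           position = 8500, width = 200),
                            clustering = 0, clusterSd = 500, seed = 1L) {
  if (is.null(barrier)) barrier <- list()
  new("LandscapeConfig", nPatches = as.integer(nPatches),
      extent = as.numeric(extent), medianHa = medianHa, sigmaLog = sigmaLog,
      minHa = minHa, maxHa = maxHa, minMappedHa = minMappedHa,
      barrier = barrier, clustering = clustering, clusterSd = clusterSd,
      seed = as.integer(seed))
}

# run expr with a local RNG seeded at `seed`, restoring the caller's state
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample patch sizes from the truncated lognormal size law
#'
#' Draws `nPatches` sizes (ha) by inverse-CDF sampling of the lognormal
#' restricted to `[minHa, maxHa]`; deterministic given the config seed.
#'
#' @param config a [LandscapeConfig-class].
#' @return numeric vector of areas in hectares, all within the
#'   truncation bounds.
#' @export
samplePatchSizes <- function(config) {
  stopifnot(is(config, "LandscapeConfig"))
  mlog <- log(config@medianHa)
  lo <- stats::plnorm(config@minHa, mlog, config@sigmaLog)
  hi <- stats::plnorm(config@maxHa, mlog, config@sigmaLog)
  withLocalSeed(config@seed, {
    u <- stats::runif(config@nPatches, lo, hi)
    stats::qlnorm(u, mlog, config@sigmaLog)
  })
}

barrierBandsY <- function(config) {
  # vertical coordinate bands available for patch centers (horizontal
  # barrier); for a vertical barrier the same in x. NULL = full extent.
  if (length(config@barrier) == 0) return(NULL)
  b <- config@barrier
  ext <- if (b$axis == "horizontal") config@extent[2] else config@extent[1]
  lower <- c(0, b$position + b$width / 2)
  upper <- c(b$position - b$width / 2, ext)
  keep <- upper > lower
  cbind(lower = lower[keep], upper = upper[keep])
}

#' Place patches as non-overlapping squares
#'
#' Spatializes sampled sizes into an actual [PatchLayer-class]: each
#' patch is an axis-aligned square (shape detail does not enter any
#' connectivity index; only edge-to-edge distance does) placed by
#' rejection sampling - uniformly, or near an already-placed patch with
#' probability `clustering` - so that no two patches overlap and none
#' intersects the barrier strip. Patches are placed largest-first;
#' placement fails with an error (never silent overlap) after 1,000
#' rejected proposals for any single patch.
#'
#' @param sizes numeric areas in hectares, typically from
#'   [samplePatchSizes()].
#' @param config a [LandscapeConfig-class]; placement uses
#'   `config@seed + 1` so sizes and placement are independent streams.
#' @return a [PatchLayer-class] with ids 1..n matching the order of
#'   `sizes`.
#' @export
placePatches <- function(sizes, config) {
  stopifnot(is(config, "LandscapeConfig"))
  n <- length(sizes)
  W <- config@extent[1]; H <- config@extent[2]
  side <- sqrt(sizes * 1e4)
  if (sum(sizes) * 1e4 > W * H)
    stop("placement infeasible: total patch area exceeds the extent")
  bands <- barrierBandsY(config)
  horizontal <- length(config@barrier) && config@barrier$axis == "horizontal"

  ord <- order(-side)
  xmin <- numeric(n); ymin <- numeric(n)
  placedX <- numeric(0); placedY <- numeric(0); placedS <- numeric(0)

  sampleCenter <- function(s) {
    # returns c(cx, cy) respecting extent margins and the barrier bands
    freeAxis <- function(ext) stats::runif(1, s / 2, ext - s / 2)
    bandAxis <- function(ext) {
      lo <- pmax(bands[, "lower"] + s / 2, s / 2)
      hi <- pmin(bands[, "upper"] - s / 2, ext - s / 2)
      len <- pmax(0, hi - lo)
      if (all(len == 0))
        stop("placement infeasible: patch of side ", round(s),
             " m does not fit between barrier and extent")
      b <- sample.int(length(len), 1, prob = len)
      stats::runif(1, lo[b], hi[b])
    }
    if (is.null(bands)) c(freeAxis(W), freeAxis(H))
    else if (horizontal) c(freeAxis(W), bandAxis(H))
    else c(bandAxis(W), freeAxis(H))
  }

  withLocalSeed(config@seed + 1L, {
    for (i in ord) {
      s <- side[i]
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        ctr <- sampleCenter(s)
        if (config@clustering > 0 && length(placedX) &&
            stats::runif(1) < config@clustering) {
          j <- sample.int(length(placedX), 1)
          ctr <- c(placedX[j] + stats::rnorm(1, 0, config@clusterSd),
                   placedY[j] + stats::rnorm(1, 0, config@clusterSd))
          ctr <- clampCenter(ctr, s, W, H, bands, horizontal)
          if (is.null(ctr)) next
        }
        x0 <- ctr[1] - s / 2; y0 <- ctr[2] - s / 2
        if (!any(x0 < placedX + placedS & x0 + s > placedX &
                 y0 < placedY + placedS & y0 + s > placedY)) {
          xmin[i] <- x0; ymin[i] <- y0
          placedX <- c(placedX, x0); placedY <- c(placedY, y0)
          placedS <- c(placedS, s)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("placement failed after 1000 attempts for a patch of side ",
             round(side[i]), " m; extent too small for the requested mosaic")
    }
  })
  geometry <- lapply(seq_len(n), function(i)
    list(rectRing(xmin[i], ymin[i], xmin[i] + side[i], ymin[i] + side[i])))
  newPatchLayer(geometry, seq_len(n), crs = "LOCAL_CARTESIAN_METERS (synthetic)")
}

clampCenter <- function(ctr, s, W, H, bands, horizontal) {
  ctr[1] <- min(max(ctr[1], s / 2), W - s / 2)
  ctr[2] <- min(max(ctr[2], s / 2), H - s / 2)
  if (is.null(bands)) return(ctr)
  v <- if (horizontal) ctr[2] else ctr[1]
  ext <- if (horizontal) H else W
  lo <- pmax(bands[, "lower"] + s / 2, s / 2)
  hi <- pmin(bands[, "upper"] - s / 2, ext - s / 2)
  okBand <- which(lo <= hi)
  if (!length(okBand)) return(NULL)
  d <- pmin(abs(v - lo), abs(v - hi))
  inBand <- okBand[v >= lo[okBand] & v <= hi[okBand]]
  if (length(inBand) == 0) {
    b <- okBand[which.min(d[okBand])]
    v <- min(max(v, lo[b]), hi[b])
  }
  if (horizontal) ctr[2] <- v else ctr[1] <- v
  ctr
}

#' Generate a district layer with a center-peaked population gradient
#'
#' Tiles the extent with a rectangular grid of districts and assigns
#' each a population from a radially decaying density model: log10
#' density falls linearly with distance from the extent center, scaled
#' between `densityRange[2]` (center) and `densityRange[1]` (farthest
#' district). The default anchors, 14,025 and 83.1 people/km2, span the
#' density contrast between a dense urban core and its suburbs.
#'
#' @param config a [LandscapeConfig-class] (only the extent is used).
#' @param nDistricts target number of districts (>= 2); realised as a
#'   near-square grid, so the actual count is `round(sqrt(n))^2`-ish.
#' @param densityRange numeric length-2 `(min, max)` density anchors in
#'   people/km2.
#' @return a [DistrictLayer-class]; deterministic (no randomness).
#' @export
generateDistricts <- function(config, nDistricts = 25,
                              densityRange = c(83.1, 14025)) {
  stopifnot(is(config, "LandscapeConfig"))
  if (nDistricts < 2) stop("nDistricts must be >= 2")
  stopifnot(length(densityRange) == 2, all(densityRange > 0),
            densityRange[1] <= densityRange[2])
  W <- config@extent[1]; H <- config@extent[2]
  gx <- max(1L, as.integer(round(sqrt(nDistricts))))
  gy <- max(2L, as.integer(ceiling(nDistricts / gx)))
  xs <- seq(0, W, length.out = gx + 1)
  ys <- seq(0, H, length.out = gy + 1)
  grid <- expand.grid(ix = seq_len(gx), iy = seq_len(gy))
  geometry <- lapply(seq_len(nrow(grid)), function(k)
    list(rectRing(xs[grid$ix[k]], ys[grid$iy[k]],
                  xs[grid$ix[k] + 1], ys[grid$iy[k] + 1])))
  cx <- (xs[grid$ix] + xs[grid$ix + 1]) / 2
  cy <- (ys[grid$iy] + ys[grid$iy + 1]) / 2
  r <- sqrt((cx - W / 2)^2 + (cy - H / 2)^2)
  rmax <- max(r)
  ld <- log10(densityRange[2]) +
    (log10(densityRange[1]) - log10(densityRange[2])) *
    (if (rmax > 0) r / rmax else 0)
  density <- 10^ld                             # people / km2
  areaM2 <- vapply(geometry, geomArea, numeric(1))
  population <- round(density * areaM2 / 1e6)
  new("DistrictLayer", districtId = seq_len(nrow(grid)),
      geometry = geometry, population = as.numeric(population),
      area = areaM2)
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper: samples sizes, places patches and tiles
#' districts from one configuration.
#'
#' @param config a [LandscapeConfig-class].
#' @param nDistricts,densityRange passed to [generateDistricts()].
#' @return list with elements `patches` ([PatchLayer-class]) and
#'   `districts` ([DistrictLayer-class]).
#' @export
synthesizeLandscape <- function(config = landscapeConfig(),
                                nDistricts = 25,
                                densityRange = c(83.1, 14025)) {
  sizes <- samplePatchSizes(config)
  list(patches = placePatches(sizes, config),
       districts = generateDistricts(config, nDistricts, densityRange))
}
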