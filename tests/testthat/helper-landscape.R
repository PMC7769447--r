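# The default synthetic landscape (the package's standing study
# conditions) is expensive at the 1000 m threshold, so it is built once
# per test run and shared across test files.

.landscapeCache <- new.env(parent = emptyenv())

defaultLandscape <- function() {
  if (is.null(.landscapeCache$land)) {
    cfg <- landscapeConfig(seed = 1)
    layer <- placePatches(samplePatchSizes(cfg), cfg)
    edges <- pairwiseEdgeDistances(layer, cutoff = 1000)
    .landscapeCache$land <- list(cfg = cfg, layer = layer, edges = edges)
  }
  .landscapeCache$land
}

defaultImportance <- function(d) {
  key <- sprintf("imp%g", d)
  if (is.null(.landscapeCache[[key]])) {
    land <- defaultLandscape()
    g <- buildThresholdGraph(land$layer, land$edges, d)
    .landscapeCache[[key]] <- nodeImportance(g)
  }
  .landscapeCache[[key]]
}
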