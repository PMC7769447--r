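#' Run the full connectivity analysis across dispersal thresholds
#'
#' Orchestrates the whole pipeline for a set of dispersal distance
#' thresholds: edge-to-edge distances are computed once with
#' `cutoff = max(thresholds)`, then for each threshold the graph is
#' built and NL, NC, the area-covering component count, the IIC
#' numerator and the per-patch importance table (dIIC with its
#' intra/flux/connector partition) are derived. With `outDir` set, the
#' artifacts are written as plain text/GeoJSON: `summary.tsv` (one row
#' per threshold, NC with the covering count in parentheses in the
#' formatted column), `importance_d<t>.tsv`, `components_d<t>.geojson`
#' (component membership per patch), `priority_d<t>.geojson`
#' (top-fraction flag), `fraction_profile.tsv` and `params.log`. On any
#' stage error, partially written outputs are removed and the error is
#' re-raised with the stage name.
#'
#' @param patches a [PatchLayer-class], a [LandscapeConfig-class]
#'   (synthesized on the fly), or a path readable by [readPatchLayer()].
#' @param thresholds dispersal distance thresholds in meters (default
#'   `c(2, 20, 44, 100, 1000)`, spanning poorly dispersed herbs to
#'   pollen-scale movement).
#' @param p coverage fraction for the area-covering component count
#'   (default 0.5).
#' @param AL optional landscape area (ha) to normalize the IIC.
#' @param outDir optional output directory (created if missing).
#' @param topQ fraction of patches flagged as priority (default 0.2).
#' @param idField forwarded to [readPatchLayer()] when `patches` is a
#'   path.
#' @return a [SweepReport-class]. The per-threshold importance tables
#'   are attached as attribute `"importance"` (a named list), and the
#'   fraction profile as attribute `"fractionProfile"`.
#' @examples
#' cfg <- landscapeConfig(nPatches = 40, extent = c(3000, 3000),
#'                        maxHa = 5, barrier = NULL, seed = 7)
#' rep <- runSweep(cfg, thresholds = c(20, 100, 1000))
#' sweepTable(rep)
#' @export
runSweep <- function(patches, thresholds = c(2, 20, 44, 100, 1000),
                     p = 0.5, AL = NULL, outDir = NULL, topQ = 0.2,
                     idField = NULL) {
  if (length(thresholds) == 0 || any(thresholds <= 0))
    stop("thresholds must be a non-empty set of positive distances")
  thresholds <- sort(unique(thresholds))
  written <- character(0)
  seed <- NA_integer_
  stage <- "input"
  result <- tryCatch({
    if (is(patches, "LandscapeConfig")) {
      seed <- patches@seed
      sourceDesc <- sprintf("synthetic landscape (n=%d, seed=%d)",
                            patches@nPatches, patches@seed)
      layer <- placePatches(samplePatchSizes(patches), patches)
    } else if (is(patches, "PatchLayer")) {
      sourceDesc <- "in-memory PatchLayer"
      layer <- patches
    } else if (is.character(patches) && length(patches) == 1) {
      sourceDesc <- patches
      layer <- readPatchLayer(patches, idField = idField)
    } else stop("patches must be a PatchLayer, LandscapeConfig or file path")

    if (!is.null(outDir) && !dir.exists(outDir))
      dir.create(outDir, recursive = TRUE)
    outFile <- function(name) {
      f <- file.path(outDir, name)
      written <<- c(written, f)
      f
    }

    stage <- "distances"
    cutoff <- max(thresholds)
    edges <- pairwiseEdgeDistances(layer, cutoff = cutoff)

    rows <- vector("list", length(thresholds))
    importance <- list()
    for (ti in seq_along(thresholds)) {
      d <- thresholds[ti]
      stage <- sprintf("graph (d=%g)", d)
      g <- buildThresholdGraph(layer, edges, d)
      part <- graphComponents(g)
      ncov <- componentsCovering(part, p)

      stage <- sprintf("indices (d=%g)", d)
      if (nPatches(layer) >= 2) {
        imp <- nodeImportance(g)
        iicNum <- attr(imp, "iicNum")
        importance[[sprintf("d%g", d)]] <- imp
      } else {
        message("importance stage skipped at d = ", d,
                ": single-patch layer (importance undefined)")
        imp <- NULL
        iicNum <- iic(g)@iicNum
      }
      iicVal <- if (!is.null(AL)) iicNum / AL^2 else NA_real_

      if (!is.null(outDir)) {
        stage <- sprintf("outputs (d=%g)", d)
        if (!is.null(imp))
          writeImportanceTable(imp, outFile(sprintf("importance_d%g.tsv", d)))
        writePatchLayer(layer,
          outFile(sprintf("components_d%g.geojson", d)),
          properties = data.frame(component = part@membership))
        if (!is.null(imp)) {
          top <- topFraction(imp, topQ)
          writePatchLayer(layer,
            outFile(sprintf("priority_d%g.geojson", d)),
            properties = data.frame(
              dIIC = round(imp$dIIC[match(layer@patchId, imp$patchId)], 6),
              priority = as.integer(layer@patchId %in% top)))
        }
      }
      rows[[ti]] <- data.frame(threshold = d, NL = numLinks(g),
                               NC = numComponents(part), NCcovering = ncov,
                               iicNum = iicNum, iic = iicVal)
    }
    stage <- "report"
    tab <- do.call(rbind, rows)
    tab$NCfmt <- sprintf("%d (%d)", tab$NC, tab$NCcovering)
    prov <- list(source = sourceDesc, nPatches = nPatches(layer),
                 totalAreaHa = sum(layer@area) / 1e4, cutoff = cutoff,
                 p = p, topQ = topQ, AL = AL,
                 version = as.character(utils::packageVersion("patchConnect")),
                 seed = seed)
    report <- new("SweepReport", table = tab, provenance = prov)

    if (!is.null(outDir)) {
      stage <- "outputs (summary)"
      writeSummaryTable(tab, outFile("summary.tsv"))
      if (length(importance)) {
        fp <- fractionProfile(importance)
        utils::write.table(format(fp, digits = 6, scientific = FALSE,
                                  trim = TRUE),
                           outFile("fraction_profile.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
      writeLines(c(sprintf("source=%s", prov$source),
                   sprintf("nPatches=%d", prov$nPatches),
                   sprintf("totalAreaHa=%.3f", prov$totalAreaHa),
                   sprintf("cutoff=%g", prov$cutoff),
                   sprintf("thresholds=%s",
                           paste(thresholds, collapse = ",")),
                   sprintf("p=%g", prov$p),
                   sprintf("topQ=%g", prov$topQ),
                   sprintf("AL=%s", ifelse(is.null(AL), "NA", AL)),
                   sprintf("version=%s", prov$version),
                   sprintf("seed=%s", seed)),
                 outFile("params.log"))
    }
    attr(report, "importance") <- importance
    attr(report, "fractionProfile") <- if (length(importance))
      fractionProfile(importance) else NULL
    report
  }, error = function(e) {
    file.remove(written[file.exists(written)])
    stop("sweep failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

writeImportanceTable <- function(imp, path) {
  out <- data.frame(patchId = imp$patchId,
                    areaHa = sprintf("%.3f", imp$areaHa),
                    dIIC = formatC(imp$dIIC, format = "g", digits = 6),
                    dIICintra = formatC(imp$dIICintra, format = "g", digits = 6),
                    dIICflux = formatC(imp$dIICflux, format = "g", digits = 6),
                    dIICconnector = formatC(imp$dIICconnector, format = "g",
                                            digits = 6),
                    rank = imp$rank,
                    normalizedRank = formatC(imp$normalizedRank, format = "g",
                                             digits = 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

writeSummaryTable <- function(tab, path) {
  out <- data.frame(threshold = tab$threshold, NL = tab$NL, NC = tab$NCfmt,
                    iicNum = formatC(tab$iicNum, format = "g", digits = 6),
                    iic = ifelse(is.na(tab$iic), "NA",
                                 formatC(tab$iic, format = "g", digits = 6)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
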