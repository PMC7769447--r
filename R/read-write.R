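#' Read a polygon habitat layer
#'
#' Reads a vector polygon layer from GeoJSON (`.geojson`/`.json`) or an
#' ESRI shapefile (`.shp`; attributes from the sibling `.dbf`, CRS check
#' from the sibling `.prj`) into a [PatchLayer-class]. Coordinates must
#' be in a projected CRS with meter units: layers that declare a
#' geographic CRS, or whose coordinates all lie inside the longitude/
#' latitude window, are refused, because all distances and areas are
#' computed in coordinate units.
#'
#' @param path path to a `.geojson`, `.json` or `.shp` file.
#' @param idField optional attribute name holding unique integer patch
#'   ids; when absent, sequential ids 1..n are assigned.
#' @return a [PatchLayer-class] with areas in m2 computed from geometry.
#' @details Polygon and MultiPolygon features are supported. Rings are
#'   re-oriented to the package convention (exterior counter-clockwise,
#'   holes clockwise); geometry validity is *not* enforced here - run
#'   [repairAndClip()] to fix self-intersections.
#' @examples
#' lay <- placePatches(c(0.5, 1), landscapeConfig(nPatches = 2, seed = 1))
#' f <- tempfile(fileext = ".geojson")
#' writePatchLayer(lay, f)
#' readPatchLayer(f)
#' @export
readPatchLayer <- function(path, idField = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    "geojson" = , "json" = readGeoJSON(path),
    "shp" = readShapefile(path),
    stop("unreadable file: unsupported vector format '.", ext, "'"))
  geometry <- parsed$geometry
  if (length(geometry) == 0) stop("empty layer: ", path)
  checkProjectedCRS(parsed$crs, geometry, path)

  if (!is.null(idField)) {
    props <- parsed$properties
    if (is.null(props) || !idField %in% names(props))
      stop("id field '", idField, "' not found in layer attributes")
    ids <- suppressWarnings(as.integer(props[[idField]]))
    if (anyNA(ids)) stop("id field '", idField, "' is not integer-valued")
    if (anyDuplicated(ids)) stop("duplicate patch id in field '", idField, "'")
  } else {
    ids <- seq_along(geometry)
  }
  newPatchLayer(geometry, ids, crs = parsed$crs)
}

checkProjectedCRS <- function(crs, geometry, path) {
  if (!is.null(crs) && !is.na(crs) && nzchar(crs)) {
    if (grepl("GEOGCS|4326|CRS84|WGS *84(?!.*UTM)", crs,
              ignore.case = TRUE, perl = TRUE) && !grepl("PROJCS", crs))
      stop("geographic CRS (degree units) refused: ", path,
           " - reproject to a metric CRS first")
  } else {
    bb <- vapply(geometry, geomBBox, numeric(4))
    if (max(abs(bb[c(1, 3), ])) <= 180 && max(abs(bb[c(2, 4), ])) <= 90)
      warning("no CRS declared and all coordinates lie within the ",
              "longitude/latitude window; assuming meters - reproject ",
              "first if the layer is geographic: ", path)
  }
  invisible(TRUE)
}

# ---- GeoJSON ---------------------------------------------------------------

readGeoJSON <- function(path) {
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("unreadable file: ", path, " (",
                                          conditionMessage(e), ")"))
  feats <- if (identical(js$type, "FeatureCollection")) js$features
           else if (identical(js$type, "Feature")) list(js)
           else stop("unreadable file: not a GeoJSON Feature(Collection)")
  crs <- NA_character_
  if (!is.null(js$crs$properties$name)) crs <- js$crs$properties$name
  geometry <- list(); props <- list()
  for (f in feats) {
    g <- f$geometry
    if (is.null(g)) next
    rings <- switch(g$type,
      "Polygon" = polygonRings(g$coordinates),
      "MultiPolygon" = do.call(c, lapply(g$coordinates, polygonRings)),
      stop("unsupported geometry type '", g$type, "' (polygons only)"))
    geometry[[length(geometry) + 1L]] <- rings
    props[[length(props) + 1L]] <- f$properties
  }
  properties <- NULL
  nm <- unique(unlist(lapply(props, names)))
  if (length(nm)) {
    properties <- as.data.frame(lapply(nm, function(k) {
      vapply(props, function(p) {
        v <- p[[k]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, character(1))
    }), col.names = nm, stringsAsFactors = FALSE)
  }
  list(geometry = geometry, properties = properties, crs = crs)
}

# one GeoJSON polygon = list(outer, hole1, ...); returns oriented open rings
polygonRings <- function(coords) {
  lapply(seq_along(coords), function(i) {
    pts <- coords[[i]]
    ring <- openRing(list(
      x = vapply(pts, function(p) as.numeric(p[[1]]), numeric(1)),
      y = vapply(pts, function(p) as.numeric(p[[2]]), numeric(1))))
    orientRing(ring, ccw = (i == 1L))
  })
}

#' Write a patch layer to GeoJSON
#'
#' Writes patches as a GeoJSON FeatureCollection with properties
#' `patch_id` and `area_ha`, plus any per-patch columns supplied in
#' `properties` (e.g. component membership or priority flags). Output is
#' deterministic: coordinates are printed with 6 decimals, so a rerun on
#' identical input is byte-identical.
#'
#' @param layer a [PatchLayer-class].
#' @param path output file path.
#' @param properties optional data.frame of extra per-patch properties
#'   (one row per patch, in layer order).
#' @return invisibly, `path`.
#' @export
writePatchLayer <- function(layer, path, properties = NULL) {
  stopifnot(is(layer, "PatchLayer"))
  if (!is.null(properties)) {
    properties <- as.data.frame(properties)
    if (nrow(properties) != nPatches(layer))
      stop("properties must have one row per patch")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  wr <- function(...) writeLines(sprintf(...), con, sep = "")
  wr('{"type":"FeatureCollection",')
  if (!is.na(layer@crs))
    wr('"crs":{"type":"name","properties":{"name":%s}},',
       jsonlite::toJSON(layer@crs, auto_unbox = TRUE))
  wr('"features":[\n')
  n <- nPatches(layer)
  for (i in seq_len(n)) {
    propStr <- sprintf('"patch_id":%d,"area_ha":%s', layer@patchId[i],
                       formatC(layer@area[i] / 1e4, format = "g", digits = 10))
    if (!is.null(properties)) {
      extra <- vapply(names(properties), function(k) {
        v <- properties[[k]][i]
        sprintf('"%s":%s', k, jsonlite::toJSON(v, auto_unbox = TRUE,
                                               digits = NA))
      }, character(1))
      propStr <- paste(c(propStr, extra), collapse = ",")
    }
    wr('{"type":"Feature","properties":{%s},"geometry":%s}%s\n', propStr,
       geomToGeoJSON(layer@geometry[[i]]), if (i < n) "," else "")
  }
  wr(']}\n')
  invisible(path)
}

geomToGeoJSON <- function(geom) {
  sgn <- vapply(geom, ringArea, numeric(1))
  outerIdx <- which(sgn >= 0)
  if (length(outerIdx) == 0) outerIdx <- 1L
  # assign each hole to the exterior ring containing its first vertex
  polys <- lapply(outerIdx, function(i) list(geom[[i]]))
  for (h in setdiff(seq_along(geom), outerIdx)) {
    hole <- geom[[h]]
    owner <- 1L
    for (oi in seq_along(outerIdx)) {
      if (pointInGeom(hole$x[1], hole$y[1], list(geom[[outerIdx[oi]]]))) {
        owner <- oi; break
      }
    }
    polys[[owner]] <- c(polys[[owner]], list(hole))
  }
  ringStr <- function(r) {
    x <- c(r$x, r$x[1]); y <- c(r$y, r$y[1])
    paste0("[", paste(sprintf("[%.6f,%.6f]", x, y), collapse = ","), "]")
  }
  polyStr <- vapply(polys, function(p)
    paste0("[", paste(vapply(p, ringStr, character(1)), collapse = ","), "]"),
    character(1))
  if (length(polys) == 1L)
    sprintf('{"type":"Polygon","coordinates":%s}', polyStr)
  else
    sprintf('{"type":"MultiPolygon","coordinates":[%s]}',
            paste(polyStr, collapse = ","))
}

# ---- ESRI shapefile (polygon subset of the spec, type 5) -------------------

readShapefile <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  code <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(code, 9994L)) stop("unreadable file: not a shapefile")
  invisible(readBin(con, "integer", 5, size = 4, endian = "big"))
  fileLen <- readBin(con, "integer", 1, size = 4, endian = "big") # 16-bit words
  invisible(readBin(con, "integer", 1, size = 4, endian = "little")) # version
  shpType <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!shpType %in% c(5L, 15L, 25L))
    stop("unsupported shapefile geometry type ", shpType, " (polygons only)")
  invisible(readBin(con, "double", 8, size = 8, endian = "little")) # bbox etc.
  geometry <- list()
  bytesRead <- 100L
  while (bytesRead < 2L * fileLen) {
    hdr <- readBin(con, "integer", 2, size = 4, endian = "big")
    if (length(hdr) < 2) break
    contentLen <- hdr[2]
    rType <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (rType == 0L) { # null shape
      bytesRead <- bytesRead + 8L + 2L * contentLen
      next
    }
    invisible(readBin(con, "double", 4, size = 8, endian = "little")) # bbox
    nParts <- readBin(con, "integer", 1, size = 4, endian = "little")
    nPoints <- readBin(con, "integer", 1, size = 4, endian = "little")
    parts <- readBin(con, "integer", nParts, size = 4, endian = "little")
    pts <- readBin(con, "double", 2 * nPoints, size = 8, endian = "little")
    # skip any Z/M payload remaining in this record
    consumed <- 4L + 32L + 8L + 4L * nParts + 16L * nPoints
    extra <- 2L * contentLen - consumed
    if (extra > 0) invisible(readBin(con, "raw", extra))
    x <- pts[seq(1, 2 * nPoints, by = 2)]
    y <- pts[seq(2, 2 * nPoints, by = 2)]
    ends <- c(parts[-1], nPoints)
    rings <- lapply(seq_len(nParts), function(p) {
      idx <- seq.int(parts[p] + 1L, ends[p])
      ring <- openRing(list(x = x[idx], y = y[idx]))
      # shapefile convention: exterior rings clockwise, holes CCW;
      # flip to the package convention (exterior positive/CCW)
      list(x = rev(ring$x), y = rev(ring$y))
    })
    # degenerate writers emit everything CCW; then treat all rings as outer
    if (all(vapply(rings, ringArea, numeric(1)) < 0))
      rings <- lapply(rings, orientRing, ccw = TRUE)
    geometry[[length(geometry) + 1L]] <- rings
    bytesRead <- bytesRead + 8L + 2L * contentLen
  }
  properties <- NULL
  dbf <- sub("\\.shp$", ".dbf", path, ignore.case = TRUE)
  if (file.exists(dbf))
    properties <- foreign::read.dbf(dbf, as.is = TRUE)
  crs <- NA_character_
  prj <- sub("\\.shp$", ".prj", path, ignore.case = TRUE)
  if (file.exists(prj))
    crs <- paste(readLines(prj, warn = FALSE), collapse = " ")
  list(geometry = geometry, properties = properties, crs = crs)
}
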