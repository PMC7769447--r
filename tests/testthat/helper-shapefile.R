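# Minimal ESRI shapefile (type 5) writer, used only to generate
# synthetic on-disk fixtures for the reader tests at test time.

writeTestShapefile <- function(path, geoms, ids = seq_along(geoms),
                               prj = NULL) {
  closeRing <- function(r) list(x = c(r$x, r$x[1]), y = c(r$y, r$y[1]))
  # shapefile convention: exterior rings clockwise -> reverse our CCW rings
  shpRings <- lapply(geoms, function(g)
    lapply(g, function(r) closeRing(list(x = rev(r$x), y = rev(r$y)))))

  recs <- lapply(shpRings, function(rings) {
    npts <- sum(vapply(rings, function(r) length(r$x), integer(1)))
    nparts <- length(rings)
    contentLen <- (4L + 32L + 8L + 4L * nparts + 16L * npts) / 2L
    list(rings = rings, npts = npts, nparts = nparts,
         contentLen = as.integer(contentLen))
  })
  allx <- unlist(lapply(shpRings, function(g) lapply(g, `[[`, "x")))
  ally <- unlist(lapply(shpRings, function(g) lapply(g, `[[`, "y")))
  fileLen <- 50L + sum(vapply(recs, function(r) 4L + r$contentLen,
                              integer(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(9994L, con, size = 4, endian = "big")
  writeBin(integer(5), con, size = 4, endian = "big")
  writeBin(fileLen, con, size = 4, endian = "big")
  writeBin(1000L, con, size = 4, endian = "little")
  writeBin(5L, con, size = 4, endian = "little")
  writeBin(c(min(allx), min(ally), max(allx), max(ally), 0, 0, 0, 0),
           con, size = 8, endian = "little")
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    writeBin(as.integer(i), con, size = 4, endian = "big")
    writeBin(r$contentLen, con, size = 4, endian = "big")
    writeBin(5L, con, size = 4, endian = "little")
    xs <- unlist(lapply(r$rings, `[[`, "x"))
    ys <- unlist(lapply(r$rings, `[[`, "y"))
    writeBin(c(min(xs), min(ys), max(xs), max(ys)), con, size = 8,
             endian = "little")
    writeBin(c(r$nparts, r$npts), con, size = 4, endian = "little")
    offs <- cumsum(c(0L, vapply(r$rings, function(rr) length(rr$x),
                                integer(1))))
    writeBin(as.integer(offs[seq_len(r$nparts)]), con, size = 4,
             endian = "little")
    writeBin(as.double(rbind(xs, ys)), con, size = 8, endian = "little")
  }
  dbf <- sub("\\.shp$", ".dbf", path)
  foreign::write.dbf(data.frame(pid = as.integer(ids)), dbf)
  if (!is.null(prj))
    writeLines(prj, sub("\\.shp$", ".prj", path))
  invisible(path)
}
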