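#' Conefor-style node and connection files
#'
#' Writes (and reads back) the plain-text input format of the Conefor
#' connectivity software: a node file with one line per patch
#' (`id<TAB>area`, area in hectares) and a connection file with one line
#' per pair (`id_a<TAB>id_b<TAB>distance`, distance in meters). Numbers
#' are printed with 8 significant digits, so a write/read round trip
#' reproduces areas and distances well within 1e-6 relative.
#'
#' @param layer a [PatchLayer-class].
#' @param edges an [EdgeList-class] whose ids all occur in `layer`.
#' @param nodePath,connectionPath output (input) file paths.
#' @return `writeConeforFiles`: invisibly, the two paths.
#'   `readConeforFiles`: a list with `nodes` (data.frame `id`, `area`
#'   in m2) and `edges` (an [EdgeList-class]; its cutoff is the largest
#'   distance present).
#' @examples
#' lay <- placePatches(c(1, 2), landscapeConfig(nPatches = 2, seed = 1))
#' ed <- pairwiseEdgeDistances(lay, cutoff = 20000)
#' nf <- tempfile(); cf <- tempfile()
#' writeConeforFiles(lay, ed, nf, cf)
#' readConeforFiles(nf, cf)$nodes
#' @export
writeConeforFiles <- function(layer, edges, nodePath, connectionPath) {
  stopifnot(is(layer, "PatchLayer"), is(edges, "EdgeList"))
  unknown <- setdiff(c(edges@from, edges@to), layer@patchId)
  if (length(unknown))
    stop("connection file would reference unknown id: ",
         paste(unknown, collapse = ", "))
  writeLines(sprintf("%d\t%s", layer@patchId,
                     formatC(layer@area / 1e4, format = "g", digits = 8)),
             nodePath)
  writeLines(sprintf("%d\t%d\t%s", edges@from, edges@to,
                     formatC(edges@distance, format = "g", digits = 8)),
             connectionPath)
  invisible(c(node = nodePath, connection = connectionPath))
}

#' @rdname writeConeforFiles
#' @export
readConeforFiles <- function(nodePath, connectionPath) {
  nodes <- utils::read.table(nodePath, header = FALSE, sep = "\t",
                             col.names = c("id", "area"))
  nodes$id <- as.integer(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate patch id in node file")
  nodes$area <- nodes$area * 1e4  # file stores hectares
  conn <- if (file.size(connectionPath) > 0)
    utils::read.table(connectionPath, header = FALSE, sep = "\t",
                      col.names = c("from", "to", "distance"))
  else data.frame(from = integer(0), to = integer(0), distance = numeric(0))
  unknown <- setdiff(c(conn$from, conn$to), nodes$id)
  if (length(unknown))
    stop("connection file references unknown id: ",
         paste(unknown, collapse = ", "))
  from <- as.integer(conn$from); to <- as.integer(conn$to)
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  cutoff <- if (length(conn$distance)) max(conn$distance) else Inf
  list(nodes = nodes,
       edges = new("EdgeList", from = from, to = to,
                   distance = conn$distance, cutoff = cutoff))
}
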