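#' Integral Index of Connectivity (IIC)
#'
#' Computes \deqn{IIC = \frac{\sum_i \sum_j a_i a_j / (1 + nl_{ij})}{A_L^2}}
#' over all ordered patch pairs (including \eqn{i = j}), where \eqn{a_i}
#' is patch area (ha), \eqn{nl_{ij}} the minimum number of links between
#' patches i and j in the threshold graph, and pairs in different
#' components contribute zero. The numerator (ha2) is always reported;
#' the normalized index in (0, 1] is filled only when the total
#' landscape area `AL` is supplied, since habitat-only studies commonly
#' report the numerator.
#'
#' @param g a [ThresholdGraph-class] (node areas in m2; converted to ha
#'   internally).
#' @param AL optional total landscape area in hectares (> 0).
#' @return an [IICResult-class].
#' @examples
#' nodes <- data.frame(id = 1:3, area = rep(1e4, 3))  # 1 ha each
#' ed <- new("EdgeList", from = c(1L, 2L), to = c(2L, 3L),
#'           distance = c(1, 1), cutoff = 10)
#' iic(buildThresholdGraph(nodes, ed, d = 10))  # numerator 17/3 ha^2
#' @export
iic <- function(g, AL = NULL) {
  stopifnot(is(g, "ThresholdGraph"))
  res <- cpp_iic_engine(g@nodeArea / 1e4, linkIndexMatrix(g),
                        importance = FALSE)
  iicNum <- res$iic_num
  iicVal <- NA_real_
  if (!is.null(AL)) {
    if (!is.numeric(AL) || length(AL) != 1 || AL <= 0)
      stop("AL must be a single landscape area > 0 (hectares)")
    if (AL^2 < iicNum)
      warning("inconsistent input: habitat connectivity numerator exceeds ",
              "AL^2 (habitat area larger than the landscape?)")
    iicVal <- iicNum / AL^2
  }
  new("IICResult", threshold = g@threshold, iicNum = iicNum,
      iic = iicVal, AL = if (is.null(AL)) NA_real_ else AL)
}

#' Per-patch importance (dIIC) and its intra/flux/connector partition
#'
#' The importance of patch k is the percentage drop of the IIC when k
#' and its links are removed:
#' \deqn{dIIC_k = 100 (IIC - IIC_{-k}) / IIC.}
#' It decomposes exactly into three non-negative fractions computed from
#' the pair terms of the IIC numerator:
#' \itemize{
#'   \item intra: the within-patch term \eqn{100 a_k^2 / num} - habitat
#'     the patch provides by itself;
#'   \item flux: \eqn{100 \cdot 2 \sum_{j \ne k} a_k a_j/(1 + nl_{kj}) / num}
#'     - connections in which the patch is an endpoint;
#'   \item connector: the loss incurred by *other* pairs when the patch
#'     no longer serves as a stepping stone (shortest-path link counts
#'     recomputed without k; pairs that become unreachable lose their
#'     full term).
#' }
#' Because dIIC is a ratio of numerators, it does not depend on the
#' landscape area \eqn{A_L}.
#'
#' @param g a [ThresholdGraph-class] with at least 2 patches.
#' @return a data.frame (one row per patch): `patchId`, `areaHa`,
#'   `dIIC`, `dIICintra`, `dIICflux`, `dIICconnector` (all in percent of
#'   the intact IIC), `rank` (1 = most important; ties broken by larger
#'   area, then smaller id) and `normalizedRank` (`dIIC / max(dIIC)`,
#'   in \[0, 1\]). Attributes `threshold` and `iicNum` carry the graph
#'   threshold and the intact IIC numerator (ha2).
#' @examples
#' nodes <- data.frame(id = 1:3, area = rep(1e4, 3))
#' ed <- new("EdgeList", from = c(1L, 2L), to = c(2L, 3L),
#'           distance = c(1, 1), cutoff = 10)
#' nodeImportance(buildThresholdGraph(nodes, ed, d = 10))
#' @export
nodeImportance <- function(g) {
  stopifnot(is(g, "ThresholdGraph"))
  n <- length(g@nodeId)
  if (n < 2)
    stop("node importance is undefined for a single-patch graph ",
         "(removal of the only node)")
  areasHa <- g@nodeArea / 1e4
  res <- cpp_iic_engine(areasHa, linkIndexMatrix(g), importance = TRUE)
  num <- res$iic_num
  intra <- 100 * res$intra / num
  flux <- 100 * res$flux / num
  connector <- 100 * res$connector / num
  dIIC <- intra + flux + connector
  rk <- integer(n)
  rk[order(-dIIC, -areasHa, g@nodeId)] <- seq_len(n)
  out <- data.frame(patchId = g@nodeId, areaHa = areasHa, dIIC = dIIC,
                    dIICintra = intra, dIICflux = flux,
                    dIICconnector = connector, rank = rk,
                    normalizedRank = dIIC / max(dIIC))
  attr(out, "threshold") <- g@threshold
  attr(out, "iicNum") <- num
  out
}

#' Mean relative contribution of the dIIC fractions per threshold
#'
#' Recasts, for every patch, the intra/flux/connector fractions as
#' percentages of that patch's own dIIC (three shares summing to 100)
#' and averages them (unweighted) across patches, one row per dispersal
#' threshold. Patches with dIIC = 0 have undefined shares and are
#' excluded from the averaging.
#'
#' @param tables a single importance table from [nodeImportance()] or a
#'   list of them (one per threshold).
#' @return data.frame with columns `threshold`, `nPatches` (number of
#'   patches averaged), `intraShare`, `fluxShare`, `connectorShare`
#'   (percent; each row sums to 100).
#' @export
fractionProfile <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  rows <- lapply(tables, function(tab) {
    stopifnot(is.data.frame(tab), "dIIC" %in% names(tab))
    thr <- attr(tab, "threshold")
    use <- tab$dIIC > 0
    tab <- tab[use, , drop = FALSE]
    shares <- 100 * cbind(tab$dIICintra, tab$dIICflux, tab$dIICconnector) /
      tab$dIIC
    m <- colMeans(shares)
    data.frame(threshold = thr %||% NA_real_,
               nPatches = nrow(tab), intraShare = m[1], fluxShare = m[2],
               connectorShare = m[3])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
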