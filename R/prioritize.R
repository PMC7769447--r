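#' Top-priority patches by dIIC
#'
#' Selects the `ceiling(q * n)` patches with the highest dIIC under the
#' deterministic tie-break of [nodeImportance()] (larger area, then
#' smaller id).
#'
#' @param table an importance table from [nodeImportance()].
#' @param q fraction in (0, 1]; e.g. `q = 0.2` flags the 20% most
#'   important patches.
#' @return integer vector of patch ids.
#' @export
topFraction <- function(table, q = 0.2) {
  stopifnot(is.data.frame(table), all(c("patchId", "rank") %in% names(table)))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1)
    stop("q must be a single fraction in (0, 1]")
  k <- ceiling(q * nrow(table))
  table$patchId[table$rank <= k]
}

#' Spearman correlations among area, dIIC and its fractions
#'
#' Rank correlation matrix (average ranks for ties) between patch area,
#' dIIC and the intra/flux/connector fractions, with two-sided p-values.
#' With `mask = TRUE`, correlations with `p >= alpha` are reported as
#' `NA` ("only significant correlations"), mirroring common reporting
#' practice; the unmasked matrix is always in `rho`.
#'
#' @param table an importance table from [nodeImportance()] with at
#'   least 5 rows.
#' @param alpha significance level for masking (default 0.05).
#' @param mask logical; if `TRUE`, `masked` contains the thresholded
#'   matrix.
#' @return list with `variables`, symmetric matrices `rho` and `p`
#'   (diagonal rho = 1, p = 0), optional `masked`, `threshold`, and
#'   `dropped` (variables with zero variance, for which rho is
#'   undefined and reported as `NA`).
#' @export
correlationMatrix <- function(table, alpha = 0.05, mask = FALSE) {
  stopifnot(is.data.frame(table))
  if (nrow(table) < 5) stop("need at least 5 patches for correlations")
  vars <- c(area = "areaHa", dIIC = "dIIC", intra = "dIICintra",
            flux = "dIICflux", connector = "dIICconnector")
  stopifnot(all(vars %in% names(table)))
  x <- as.matrix(table[, vars])
  colnames(x) <- names(vars)
  k <- ncol(x)
  rho <- matrix(NA_real_, k, k, dimnames = list(names(vars), names(vars)))
  pmat <- rho
  constant <- apply(x, 2, function(v) length(unique(v)) == 1L)
  diag(rho) <- 1; diag(pmat) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      if (constant[i] || constant[j]) next  # rho undefined, stays NA
      ct <- suppressWarnings(
        stats::cor.test(x[, i], x[, j], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
  }
  out <- list(variables = names(vars), rho = rho, p = pmat,
              threshold = attr(table, "threshold"),
              dropped = names(vars)[constant])
  if (mask) {
    masked <- rho
    masked[pmat >= alpha] <- NA_real_
    out$masked <- masked
    out$alpha <- alpha
  }
  out
}

#' Green-space area per capita by district
#'
#' Distributes patch area over districts by exact polygon intersection
#' (a patch straddling districts contributes each part to its district)
#' and derives, per district, the habitat area per inhabitant and the
#' population density.
#'
#' @param patches a [PatchLayer-class].
#' @param districts a [DistrictLayer-class] with populations > 0 for
#'   every district that should enter per-capita ratios (districts with
#'   population 0 get `areaPerCapita = NA`).
#' @return data.frame with one row per district: `districtId`,
#'   `grasslandM2` (habitat area inside the district, m2), `population`,
#'   `areaPerCapita` (m2 per person), `densityKm2` (people per km2) and
#'   `districtAreaM2`.
#' @export
perCapita <- function(patches, districts) {
  stopifnot(is(patches, "PatchLayer"), is(districts, "DistrictLayer"))
  nd <- length(districts@districtId)
  dbb <- vapply(districts@geometry, geomBBox, numeric(4))
  pbb <- vapply(patches@geometry, geomBBox, numeric(4))
  grass <- numeric(nd)
  for (i in seq_len(nPatches(patches))) {
    cand <- which(pbb[1, i] < dbb[3, ] & pbb[3, i] > dbb[1, ] &
                  pbb[2, i] < dbb[4, ] & pbb[4, i] > dbb[2, ])
    for (j in cand) {
      inter <- polyclip::polyclip(patches@geometry[[i]],
                                  districts@geometry[[j]],
                                  op = "intersection",
                                  fillA = "evenodd", fillB = "evenodd",
                                  eps = clipperEps(patches@geometry[[i]],
                                                   districts@geometry[[j]]))
      if (length(inter))
        grass[j] <- grass[j] + sum(vapply(inter, ringArea, numeric(1)))
    }
  }
  apc <- ifelse(districts@population > 0, grass / districts@population,
                NA_real_)
  data.frame(districtId = districts@districtId, grasslandM2 = grass,
             population = districts@population, areaPerCapita = apc,
             densityKm2 = districts@population / (districts@area / 1e6),
             districtAreaM2 = districts@area)
}

#' Density vs. per-capita green space, on log-log scale
#'
#' Relates district population density to green-space area per capita:
#' Spearman rank correlation (with two-sided p) plus the ordinary
#' least-squares slope of `log10(areaPerCapita) ~ log10(densityKm2)`.
#' Districts with zero population or zero habitat (log undefined) are
#' excluded.
#'
#' @param pcTable output of [perCapita()].
#' @return list with `rho`, `p`, `slope`, `intercept` and `n` (number of
#'   districts used).
#' @export
logLogRelation <- function(pcTable) {
  stopifnot(is.data.frame(pcTable),
            all(c("areaPerCapita", "densityKm2") %in% names(pcTable)))
  use <- is.finite(pcTable$areaPerCapita) & pcTable$areaPerCapita > 0 &
    is.finite(pcTable$densityKm2) & pcTable$densityKm2 > 0
  x <- log10(pcTable$densityKm2[use])
  y <- log10(pcTable$areaPerCapita[use])
  if (length(x) < 3) stop("need at least 3 districts with positive density ",
                          "and per-capita area")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  fit <- stats::lm(y ~ x)
  list(rho = unname(ct$estimate), p = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x))
}
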