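---
title: "Habitat graphs, the IIC, and patch prioritization: methods and design"
author: "patchConnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat graphs, the IIC, and patch prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`patchConnect` models *structural* connectivity of a habitat mosaic
under *functional* (species-group) assumptions. The habitat is a set of
polygons in a projected, metric coordinate system. A species group is
summarized by a single dispersal distance threshold $d$: propagules are
assumed to move freely within a patch (intrapatch connectivity) and to
cross gaps of at most $d$ meters between patch boundaries. The mosaic
then becomes an undirected graph: patches are nodes with their areas
$a_i$ as attributes, and an unweighted link joins every pair whose
minimum edge-to-edge Euclidean distance is at most $d$. Everything else
in the package is a function of this graph, recomputed per threshold.

Three structural descriptors summarize a threshold graph:

* $NL$, the number of links, and $NC$, the number of connected
  components (an isolated patch is a component of size one);
* the *area-covering component count*: the smallest $k$ such that the
  $k$ largest components together hold strictly more than a fraction
  $p$ (default $0.5$) of total habitat area. When patch sizes are
  heavily right-skewed, a handful of components may hold most of the
  habitat while $NC$ is dominated by tiny isolates; this count reads
  the landscape the way a population would.

Overall connectivity is measured by the Integral Index of Connectivity

$$IIC = \frac{\sum_i \sum_j a_i a_j / (1 + nl_{ij})}{A_L^2},$$

with $nl_{ij}$ the minimum number of links on a path between patches
$i$ and $j$ ($nl_{ii} = 0$), pairs in different components contributing
zero, and $A_L$ the total landscape area. The numerator has units of
area squared (ha² here) and is the quantity the package reports by
default; dividing by $A_L^2$ is a display choice that cancels from
every patch-importance ratio, so `iic()` makes it optional and
explicit. The numerator is bounded below by $\sum_i a_i^2$ (edgeless
graph) and above by $\sum_i a_i^2 + \tfrac12\sum_{i \ne j} a_i a_j$
(fully connected), both of which are asserted in the test suite.

### Patch importance and its exact partition

The importance of patch $k$ is the relative IIC loss when $k$ and its
links are removed,

$$dIIC_k = 100\,\frac{IIC - IIC_{-k}}{IIC},$$

computed not by naive re-enumeration but from the pair terms of the
numerator, which yields an exact additive partition:

* **intra**: $100\,a_k^2 / \mathrm{num}$ — habitat the patch provides
  by itself, independent of the topology;
* **flux**: $100 \cdot 2 \sum_{j \ne k} a_k a_j / (1 + nl_{kj}) /
  \mathrm{num}$ — all pair terms with $k$ as an endpoint;
* **connector**: $100 \sum_{i \ne k}\sum_{j \ne k} a_i a_j
  \left(\frac{1}{1 + nl_{ij}} - \frac{1}{1 + nl^{-k}_{ij}}\right) /
  \mathrm{num}$ — the loss remaining pairs suffer because their
  shortest paths lengthen (or vanish: a disconnected pair loses its
  full term) once $k$ is gone.

The identity $dIIC_k = \mathrm{intra}_k + \mathrm{flux}_k +
\mathrm{connector}_k$ holds exactly and is verified against a
remove-and-recompute oracle (Floyd–Warshall plus exhaustive pair
enumeration, written independently in the tests) to $10^{-9}$ relative
on randomized graph suites.

For cross-threshold comparison, `fractionProfile()` recasts each
patch's three fractions as shares of that patch's own $dIIC$ (summing
to 100) and averages them per threshold, unweighted. Patches with
$dIIC = 0$ — possible only in degenerate equal-term constellations —
have undefined shares and are excluded from the average.

### Computational notes

All shortest-path link counts are obtained by breadth-first search per
component in compiled code. For the connector fraction, recomputing
all-pairs BFS after every node removal would be quadratic in component
size; instead the engine uses shortest-path *counts* $\sigma_{ij}$
(saturating 62-bit integers, so the test errs only on the conservative
side): removing $k$ can change $nl_{ij}$ only if *every* shortest
$i$–$j$ path passes $k$, i.e. $nl_{ik} + nl_{kj} = nl_{ij}$ and
$\sigma_{ik}\sigma_{kj} = \sigma_{ij}$. BFS re-runs are restricted to
the node set passing that test, within $k$'s component only. On the
default synthetic landscape (2,000 patches; a single ~2,000-node
component at the 1000 m threshold with ~28,000 links) the full
importance table takes on the order of a minute on one CPU; the four
smaller thresholds are near-instant.

## Geometry

Inter-patch distance is the minimum boundary-to-boundary Euclidean
distance (segment-to-segment, in compiled code), not centroid distance:
centroid distance would disconnect large adjacent patches, and
edge-to-edge is the convention of the GIS tooling this workflow
replaces. Touching or overlapping patches get distance zero — they are
linked at every threshold but are *not* merged, preserving the source
map's patch delineation. Multipolygon patches are supported; distance
uses all parts. Candidate pairs come from a uniform grid index on
bounding boxes (cell size = cutoff), and the grid path is
property-tested to return exactly the brute-force all-pairs result.
Distances are computed once with cutoff $= \max(d)$ and pruned per
threshold, since thresholds only subset this superset; the threshold
comparison is *inclusive* (a pair exactly at $d$ stays linked, because
only links exceeding the threshold are eliminated), and "exceeds" in
the area-covering count is *strict*.

Polygon repair (self-intersecting "bow-tie" rings) and clipping use the
Clipper library via `polyclip`, with the even-odd fill rule so an
invalid ring resolves to the simple polygons covering the same region.
Clipper snaps coordinates to an integer grid; the package sets the
resolution to $10^{-12}$ of the coordinate span so snapping error is
orders of magnitude below the $10^{-9}$ relative tolerances the tests
assert. Areas are the shoelace sum over oriented rings (holes
negative), kept internally in m² and reported in hectares. Layers must
be in a projected CRS; a declared geographic CRS is refused, and
missing CRS metadata with degree-sized coordinates triggers a warning.

Conefor-style node (`id TAB area[ha]`) and connection
(`id TAB id TAB distance[m]`) text files are written with 8 significant
digits. Six digits — the display precision used elsewhere — would allow
round-trip errors just above $10^{-6}$ relative for unluckily placed
mantissas; 8 digits keep the documented $10^{-6}$ round-trip guarantee
with margin.

## The synthetic landscape

Connectivity studies of urban habitat are typically bound to versioned,
non-redistributable GIS extracts. The generator therefore emulates the
*statistical* structure such data share, so the full pipeline is
testable end to end:

* **Sizes**: a truncated lognormal, parameterized by its median
  (default 0.4 ha) and log-sd $\sigma$ (default 2.1), truncated to
  [0.003, 1179] ha. These defaults reproduce the signature of urban
  grassland mosaics: a sub-0.5-ha modal class holding most patches by
  count, and a handful of >100 ha patches holding a large share of
  total area. $\sigma = 2.1$ follows from matching a ~0.4 ha median
  against a ~4 ha mean (mean/median $= e^{\sigma^2/2}$). The lower
  truncation doubles as the map-resolution floor: fragments below it
  simply do not occur in source maps of this kind.
* **Placement**: axis-aligned squares placed largest-first by rejection
  sampling (uniform, or near an existing patch with probability
  `clustering`), without overlap; 1,000 rejected proposals for any
  patch is a hard error, never silent overlap. Squares suffice because
  no index in the package sees shape — only areas and edge-to-edge
  distances enter.
* **Barrier**: a 200 m wide strip across the extent (a stylized river)
  that placement avoids, so opposite banks are at least the strip width
  apart and fall into separate components for all thresholds below it,
  while long-distance (pollen-scale) thresholds bridge it.
* **Districts**: a rectangular grid tiling the extent, with population
  density decaying log-linearly with distance from the extent center
  between anchors 14,025 (core) and 83.1 (edge) people/km² — the
  density contrast of a compact European city and its suburbs.
* **Extent**: 17 × 17 km for 2,000 patches, putting expected habitat
  cover near 25–30% of the "city" area.

Everything is a pure function of the configuration (seed included);
sizes, placement and districts use separate derived seeds so changing
one stage does not reshuffle another.

What the generator deliberately does **not** emulate: real patch
shapes (elongated verges, riparian ribbons), spatial autocorrelation of
land use, the actual geometry of any city, or empirically calibrated
clustering (no published clustering statistics exist to anchor the
`clustering` knob, so it defaults to off). Passing tests on this
landscape therefore demonstrate correctness of the computations and
qualitative pattern recovery — importance tracking area, intra giving
way to flux as dispersal grows, rivers severing banks, denser districts
having less green space per head — not quantitative agreement with any
particular city's numbers.

## Other design choices

* **Ranking ties** (identical $dIIC$) break by larger area, then
  smaller id, making ranks and the top-fraction selection
  reproducible. `topFraction(q)` takes $\lceil qn \rceil$ patches.
* **Unreachable pairs** contribute exactly zero to the IIC and are
  stored as *absent* in the sparse link-count output (never a sentinel
  large number), so downstream code cannot silently misread them.
* **Correlation matrices** use Spearman rank correlation with
  average-rank ties and asymptotic two-sided p-values; a
  significance-masked view (default $\alpha = 0.05$) is available
  alongside the always-complete matrix, and zero-variance columns are
  reported as undefined rather than silently dropped.
* **Per-capita analysis** assigns a boundary-straddling patch to
  districts by exact polygon intersection (each part credited to its
  district), which makes district habitat areas exactly additive;
  zero-population districts are flagged undefined and excluded from
  the log–log density relation. The relation is reported as Spearman
  rho plus a descriptive OLS slope on $\log_{10}$ values — no
  inferential model is fitted.
* **Normalized rank**: per-patch $dIIC / \max_k dIIC$, a [0, 1]
  importance scale alongside the ordinal rank; the percentage $dIIC$
  itself is never rescaled.
* **Sweep reports** assert at construction that $NL$ is non-decreasing
  and $NC$ non-increasing across ascending thresholds — a structural
  invariant of nested graphs that guards against pipeline drift — and
  carry full provenance (source, cutoff, parameters, seed, package
  version). Written artifacts use fixed formatting (areas to 3
  decimals, indices to 6 significant digits) so reruns are
  byte-identical.

## Problem sizes and tolerances used in validation

The oracle suites run 100 random graphs of up to 60 nodes at $10^{-9}$
relative tolerance (exhaustive Floyd–Warshall enumeration is quadratic
in memory and cubic in time, which caps the oracle size, not the
engine). Full-scale properties run on the default 2,000-patch
landscape across thresholds {2, 20, 44, 100, 1000} m. Conefor
round-trips are checked at 500 patches to $10^{-6}$ relative. The
acceptance script regenerates the landscape and all headline
quantities from a single seed in under a minute.

## Known limitations

* Binary threshold links only: no probability-weighted (PC-style)
  kernels, no cost surfaces or circuit-theory resistance — the model is
  the threshold graph.
* Geometry repair handles self-intersecting rings and orientation
  errors; pathological inputs (zero-area slivers, coincident duplicate
  patches) survive only if their covered area is positive.
* No CRS transformation: inputs must already be projected in meters;
  the package validates, it does not reproject.
* Shapefile support covers polygon geometry (type 5) with `.dbf`
  attributes; exotic variants (measured/Z geometries are read by
  dropping the extra dimensions) should be converted to GeoJSON first.
* District populations are treated as exact counts; no uncertainty in
  the per-capita ratios is propagated.
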