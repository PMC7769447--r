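# patchConnect

Graph-theoretic connectivity assessment and prioritization of habitat
patches in fragmented (typically urban) landscapes.

Urban grasslands, lawns, road verges and similar habitat fragments host
plant populations whose seed and pollen move only limited distances.
Whether such a mosaic functions as a connected habitat network therefore
depends on the assumed dispersal ability of the species group.
`patchConnect` takes a polygon habitat layer, turns it into a series of
*dispersal-threshold graphs* — patches are nodes, and two patches are
linked when their minimum edge-to-edge distance does not exceed a
dispersal distance threshold *d* — and quantifies connectivity and the
contribution of every individual patch. It is aimed at landscape
ecologists and urban planners who would otherwise run this workflow
through GIS plugins and the Conefor software.

## The indices

For a threshold graph the package reports:

* **NL** — number of links, and **NC** — number of connected components
  (an isolated patch is its own component);
* **area-covering component count** — the smallest number of largest
  components whose summed area *strictly exceeds* a fraction *p*
  (default 0.5) of the total habitat area; a more informative summary
  than NC when the patch-size distribution is strongly right-skewed;
* the **Integral Index of Connectivity**

  ```
  IIC = [ Σ_i Σ_j  a_i a_j / (1 + nl_ij) ] / A_L²
  ```

  where `a_i` is patch area, `nl_ij` the number of links on the
  shortest topological path between patches *i* and *j* (pairs in
  different components contribute zero), and `A_L` the landscape area.
  The numerator (ha²) is reported as is; normalization by `A_L²` is
  optional and explicit.
* **dIIC** — the percentage drop in IIC when one patch and its links
  are removed, i.e. that patch's importance for overall connectivity,
  partitioned *exactly* into three additive fractions:
  **intra** (the patch's own area term `a_k²`), **flux** (connections
  in which the patch is an endpoint) and **connector** (the loss other
  pairs suffer when the patch stops serving as a stepping stone).

On top of the per-patch importance tables the package ranks priority
patches (e.g. the top 20% by dIIC), computes Spearman correlation
matrices between area, dIIC and its fractions, and relates district
green-space area per capita to population density.

Because connectivity studies of this kind are usually tied to
non-redistributable GIS extracts, the package ships a synthetic
landscape generator (`landscapeConfig()`, `synthesizeLandscape()`)
that emulates the statistical structure such data typically have:
~2,000 patches with truncated-lognormal sizes (median 0.4 ha, range
0.003–1179 ha), a river-like barrier strip, and districts with a
center-peaked population density gradient. Every generator output is a
pure function of its configuration, seed included.

## Worked example

```r
library(patchConnect)

## three 1-ha patches in a row, 15 m and 30 m apart
nodes <- data.frame(id = 1:3, area = c(1e4, 1e4, 1e4))   # m2
edges <- new("EdgeList", from = c(1L, 2L), to = c(2L, 3L),
             distance = c(15, 30), cutoff = 100)
g <- buildThresholdGraph(nodes, edges, d = 44)
iic(g, AL = 10)
#> IIC at d = 44 m: numerator 5.66667 ha^2, IIC = 0.0566667 (A_L = 10 ha)
nodeImportance(g)
#>   patchId areaHa  dIIC dIICintra dIICflux dIICconnector rank normalizedRank
#> 1       1      1 47.06     17.65    29.41          0.00    2         0.7273
#> 2       2      1 64.71     17.65    35.29         11.76    1         1.0000
#> 3       3      1 47.06     17.65    29.41          0.00    3         0.7273
```

The numerator 17/3 ≈ 5.667 ha² counts each patch against itself (3×1),
each adjacent pair at one link (2 × 1/2, twice), and the end pair at
two links (2 × 1/3). Removing the middle patch costs 64.7% of the IIC:
17.6 points are its own area (intra), 35.3 its direct connections
(flux), and 11.8 the stepping-stone service it provides to the end
pair (connector). The end patches are no stepping stones: their
connector fraction is zero.

A full threshold sweep over a synthetic mosaic:

```r
cfg <- landscapeConfig(nPatches = 200, extent = c(6000, 6000),
                       maxHa = 40, seed = 1)
rep <- runSweep(cfg, thresholds = c(2, 20, 44, 100, 1000))
sweepTable(rep)[, 1:5]
#>  threshold   NL  NC NCcovering    iicNum
#>          2    1 199         11  4174.345
#>         20   12 188         11  4195.752
#>         44   19 182         11  4225.978
#>        100   58 146          9  5306.864
#>       1000 1771   1          1 37975.018
attr(rep, "fractionProfile")
#>   threshold nPatches intraShare fluxShare connectorShare
#> 1         2      200     99.500       0.5       0.00e+00
#> 2        20      200     94.000       6.0       5.30e-04
#> 3        44      200     91.000       9.0       3.69e-05
#> 4       100      200     73.096      25.3       1.62e+00
#> 5      1000      200      0.896      95.6       3.52e+00
```

Links accumulate and components merge as the dispersal threshold grows;
at 2 m importance is almost purely patch size (intra ≈ 99.5%), while at
1000 m direct flux dominates. `runSweep(..., outDir = "out/")`
additionally writes the summary, per-threshold importance tables,
component / priority GeoJSON layers and a parameter log.

A command-line front end with `sweep`, `synth`, `importance` and
`percapita` verbs is installed at
`system.file("scripts", "patchconnect.R", package = "patchConnect")`.

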