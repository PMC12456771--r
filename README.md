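# skelphen

Automated stem–leaf segmentation and phenotypic trait extraction for 3D
point clouds of single-stemmed tree seedlings.

Given one merged (registered) point cloud of a seedling — gravity along
+Y, metric units — the package separates the thin stem from the foliage
and reports the four traits nursery phenotyping needs: **plant height**,
**stem length**, **stem diameter** and **per-leaf area**. It is aimed at
plant-phenotyping researchers working with bench-top multi-view depth
scans of erect broadleaf seedlings (20–60 cm, stems 2–6 mm, 4–15 leaves).

## Method

The pipeline chains five stages, each exposed as ordinary R functions:

1. **Statistical outlier removal** — drop points whose mean distance to
   their *k* nearest neighbours exceeds `mean + 1.1·sd` of that statistic
   (*k* = 100).
2. **Density-weighted voxel-centroid skeletonization** — partition on an
   *L*-grid (L₀ = 1 cm), split each cell into eight half-edge sub-cells,
   keep sub-cells with accumulated count *m* > θ (θ = 6), and emit per cell
   the weighted centroid `C_w = Σ mⱼCⱼ / Σ mⱼ`; repeat with *L* doubled.
3. **Stem extraction** — Kruskal MST over the skeleton; nodes typed by
   degree (TIP ≤ 1, INTERNAL = 2, JUNCTION ≥ 3); PCA principal line
   aligned to +Y; the highest junction within 2 cm of that line is joined
   to the root by Dijkstra's algorithm; the path is despiked, smoothed
   with a natural cubic spline, and stem points are labeled by exact
   point-to-segment radius search.
4. **Leaf instance segmentation** — VCCS supervoxels grown in a
   37-dimensional feature space (curvature, XYZ, 33-bin FPFH) under the
   similarity distance
   `D = w_c·D_c²/c_max² + w_s·D_s²/(3R_seed²) + w_n·D_n²`;
   LCCP convexity merging (β_th = 20°, θ_th = 0.1, clusters ≤ 100 points
   dropped); adherent leaves split by K-means++ with the adaptive rule
   `K = ⌊S_e/μ̄⌋` (no split when K < 2).
5. **Traits** — `H = Y_max − Y_min`; stem length as the curve's arc
   length; diameter from direct least-squares ellipse fits to four thin
   slices 5–8 cm above the stem base (2 × mean minor semi-axis); leaf area
   from triangulated leaf meshes after boundary-ring hole repair.

A synthetic seedling generator with analytic ground truth (per-point
labels, height, stem arc length, diameter, per-leaf ellipse areas) makes
the whole pipeline testable without any scan data.

## Worked example

```r
library(skelphen)

spec  <- randomPlantSpec(seed = 42)   # a 30-50 cm seedling, 5-10 leaves
plant <- generatePlant(spec)
plant$cloud
#> PlantCloud with 38963 points | bbox [-0.220,0.246]x[-0.516,1.019]x[-0.226,0.206] m
#>   labels: leaf_1=2969, leaf_2=2695, leaf_3=2496, leaf_4=2299, leaf_5=2085,
#>           leaf_6=1941, leaf_7=1723, leaf_8=1494, leaf_9=1494, outlier=200, stem=19567

report <- runPipeline(plant$cloud,
                      pipelineConfig(stem_radius = spec$stem_radius, seed = 42))
report
#> TraitReport
#>   plant height : 0.5210 m
#>   stem length  : 0.4952 m
#>   stem diameter: 0.00522 m
#>   leaf areas   : 9 leaves, total 0.018302 m^2
```

The generator's analytic truth for the same plant is height 0.5199 m, stem
length 0.4831 m, diameter 0.00516 m and total leaf area 0.018647 m² — the
pipeline recovers height within 0.2%, stem length within 2.5%, diameter
within 1.2% and total leaf area within 1.9% here. All nine leaves are
found as separate instances.

Individual stages are available directly (`sorFilter()`, `skeletonize()`,
`buildMST()`, `segmentLeaves()`, `stemDiameter()`, `triangulateLeaf()`,
...), and `runPipeline(..., keep_intermediate = TRUE)` returns every
intermediate object. A thin command-line front end lives in
`inst/cli/skelphen.R` with subcommands `generate`, `preprocess`,
`skeletonize` and `run`. PLY and PCD files are read and written with
`readCloud()` / `writePLY()` / `writePCD()`.

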