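Package: skelphen
Title: Skeleton-Based Stem-Leaf Segmentation and Phenotyping of Seedling Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Automated extraction of phenotypic traits from merged 3D point clouds of
    single-stemmed tree seedlings. Implements density-weighted voxel-centroid
    skeletonization, minimum-spanning-tree topology analysis with PCA-based stem
    identification, radius-search stem/leaf separation, supervoxel + locally convex
    connected patches (LCCP) leaf instance segmentation with adaptive K-means++
    refinement, and automatic measurement of plant height, stem length, stem diameter
    (ellipse-fitted cross sections) and leaf area (triangulated meshes with boundary-ring
    hole repair). Ships a synthetic seedling generator with analytic ground truth so the
    entire pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
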