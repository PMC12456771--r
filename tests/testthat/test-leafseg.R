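test_that("normals and curvature behave on planes and spheres", {
  g <- as.matrix(expand.grid(seq(0, 0.05, 0.005), seq(0, 0.05, 0.005)))
  plane <- cbind(g[, 1], 0.02, g[, 2])
  nc <- normalsCurvature(plane, k = 8)
  expect_lt(max(abs(abs(nc$normals[, 2]) - 1)), 1e-6)  # normal || Y
  expect_lt(max(nc$curvature), 1e-6)
  # sphere sample: normals within 5 degrees of radial
  set.seed(2)
  u <- matrix(rnorm(3 * 3000), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sph <- 0.05 * u
  nc2 <- normalsCurvature(sph, k = 24)
  cosang <- abs(rowSums(nc2$normals * u))
  expect_gt(min(cosang), cos(5 * pi / 180))
  # curvature bounded by the eigenvalue-ratio limit
  expect_true(all(nc2$curvature >= 0 & nc2$curvature <= 1 / 3 + 1e-12))
})

test_that("FPFH is translation-invariant, block-normalized, discriminative", {
  # near-exact translation invariance: the only admissible differences come
  # from Darboux source-selection ties on coplanar pairs, which can flip
  # under 1e-16 eigenvector perturbations and move single counts across bins
  set.seed(5)
  patch <- cbind(runif(150, 0, 0.03), runif(150, 0, 0.001),
                 runif(150, 0, 0.03))
  shifted <- sweep(patch, 2, c(1, 2, 3), "+")
  nc <- normalsCurvature(patch, k = 10)
  f1 <- fpfh(patch, nc$normals, 0.008)
  nc2 <- normalsCurvature(shifted, k = 10)
  f2 <- fpfh(shifted, nc2$normals, 0.008)
  expect_lt(mean(abs(f1 - f2)), 0.5)
  expect_identical(f1, fpfh(patch, nc$normals, 0.008))  # deterministic
  sums <- sapply(0:2, function(b) rowSums(f1[, b * 11 + 1:11]))
  expect_true(all(abs(sums - 100) < 1e-9 | sums == 0))
  # plane point vs 90-degree roof-edge point separate in L1
  xs <- seq(-0.02, 0.02, 0.001)
  roof <- cbind(rep(xs, 21), abs(rep(xs, 21)),
                rep(seq(-0.01, 0.01, 0.001), each = 41))
  ncr <- normalsCurvature(roof, k = 8)
  fr <- fpfh(roof, ncr$normals, 0.004)
  edge_i <- which.min(abs(roof[, 1]) + abs(roof[, 3]))
  flat_i <- which.max(roof[, 1])
  expect_gt(sum(abs(fr[edge_i, ] - fr[flat_i, ])), 0)
})

test_that("the supervoxel similarity distance reproduces hand evaluation", {
  cfg <- vccsConfig()  # defaults: R_voxel 8 mm, R_seed 10 mm, w = (0.2,0.4,1)
  expect_equal(cfg$R_voxel, 0.008)
  expect_equal(cfg$R_seed, 0.01)
  expect_equal(vccsDistance(0, 0, 0, cfg, c_max = 0.2), 0)
  expect_equal(vccsDistance(0.1, 0.01, 0.25, cfg, c_max = 0.2),
               0.2 * 0.25 + 0.4 / 3 + 0.0625, tolerance = 1e-12)
})

test_that("supervoxels partition the cloud and respect connectivity", {
  pl <- generatePlant(plantSpec(n_leaves = 4, outlier_count = 0, seed = 13))
  lab <- pointLabels(pl$cloud)
  leaf <- coords(pl$cloud)[grepl("^leaf", lab), , drop = FALSE]
  sv <- vccsSupervoxels(leaf)
  expect_true(all(sv$point_label >= 1))          # every point assigned
  expect_equal(length(sv$point_label), nrow(leaf))
  # adjacency is symmetric
  for (i in seq_len(sv$n))
    for (j in sv$adjacency[[i]])
      expect_true(i %in% sv$adjacency[[j]])
  # two coplanar patches 10 seed-widths apart never share a supervoxel
  far <- rbind(cbind(runif(200, 0, 0.02), 0, runif(200, 0, 0.02)),
               cbind(runif(200, 0.12, 0.14), 0, runif(200, 0, 0.02)))
  sv2 <- vccsSupervoxels(far)
  left <- unique(sv2$point_label[1:200])
  right <- unique(sv2$point_label[201:400])
  expect_length(intersect(left, right), 0)
})

test_that("LCCP merges convex/coplanar and cuts concave contacts", {
  mkSV <- function(normals, centroids, sizes = c(200, 200)) {
    structure(list(point_label = rep(1:2, sizes), voxel_label = 1:2,
                   centroid = centroids, normal = normals,
                   curvature = c(0, 0), fpfh = matrix(0, 2, 33),
                   size = sizes, adjacency = list(2L, 1L), n = 2L),
              class = "Supervoxels")
  }
  cfg <- lccpConfig(min_cluster_points = 0)
  # coplanar neighbours (identical normals) merge
  co <- mkSV(rbind(c(0, 1, 0), c(0, 1, 0)),
             rbind(c(0, 0, 0), c(0.01, 0, 0)))
  expect_equal(length(unique(lccpMerge(co, cfg)$point_label)), 1)
  # 90-degree concave valley (normals converging) stays cut
  valley <- mkSV(rbind(c(1, 1, 0) / sqrt(2), c(-1, 1, 0) / sqrt(2)),
                 rbind(c(-0.01, 0.01, 0), c(0.01, 0.01, 0)))
  expect_equal(length(unique(lccpMerge(valley, cfg)$point_label)), 2)
  # the same dihedral as a convex roof (normals diverging) merges
  roof <- mkSV(rbind(c(-1, 1, 0) / sqrt(2), c(1, 1, 0) / sqrt(2)),
               rbind(c(-0.01, 0.01, 0), c(0.01, 0.01, 0)))
  expect_equal(length(unique(lccpMerge(roof, cfg)$point_label)), 1)
  # the default size filter drops an 80-point cluster
  small <- mkSV(rbind(c(1, 1, 0) / sqrt(2), c(-1, 1, 0) / sqrt(2)),
                rbind(c(-0.01, 0.01, 0), c(0.01, 0.01, 0)),
                sizes = c(80, 200))
  out <- lccpMerge(small, lccpConfig())  # default min_cluster_points = 100
  expect_true(all(out$point_label[1:80] == 0))
  expect_true(all(out$point_label[81:280] == 1))
})

test_that("lccp clustering is invariant to supervoxel id permutation", {
  pl <- generatePlant(plantSpec(n_leaves = 3, outlier_count = 0, seed = 17))
  lab <- pointLabels(pl$cloud)
  leaf <- coords(pl$cloud)[grepl("^leaf", lab), , drop = FALSE]
  sv <- vccsSupervoxels(leaf)
  base <- lccpMerge(sv)$point_label
  set.seed(42)
  perm <- sample(sv$n)
  inv <- integer(sv$n); inv[perm] <- seq_len(sv$n)
  sv2 <- sv
  sv2$point_label <- inv[sv$point_label]
  sv2$voxel_label <- inv[sv$voxel_label]
  sv2$centroid <- sv$centroid[perm, ]; sv2$normal <- sv$normal[perm, ]
  sv2$curvature <- sv$curvature[perm]; sv2$fpfh <- sv$fpfh[perm, ]
  sv2$size <- sv$size[perm]
  sv2$adjacency <- lapply(sv$adjacency[perm], function(v) sort(inv[v]))
  pp <- lccpMerge(sv2)$point_label
  # same partition: label vectors agree up to renaming
  tab <- table(base, pp)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("adaptive K reproduces the floor rule", {
  k1 <- adaptiveK(c(100, 100, 250))
  expect_equal(attr(k1, "mean_size"), 150)
  expect_identical(k1$k, c(1L, 1L, 1L))   # K = floor(250/150) = 1 -> keep
  k2 <- adaptiveK(c(100, 100, 500))
  expect_identical(k2$k, c(1L, 1L, 2L))   # K = floor(500/233.3) = 2 -> split
  expect_identical(adaptiveK(c(300, 300, 300))$k, rep(1L, 3))
  # randomized vectors against the one-line oracle
  set.seed(3)
  for (i in 1:20) {
    s <- sample(50:5000, sample(2:12, 1))
    got <- adaptiveK(s)$k
    mu <- mean(s)
    want <- ifelse(s > mu & floor(s / mu) >= 2, floor(s / mu), 1)
    expect_identical(got, as.integer(want))
  }
})

test_that("K-means++ separates blobs and obeys its defaults", {
  cfg <- kmeansConfig()
  expect_identical(cfg$max_iter, 100L)
  expect_equal(cfg$tol, 0.001)         # 0.1 cm convergence threshold
  expect_equal(cfg$min_center_sep, 0.002)
  set.seed(1)
  blob1 <- matrix(rnorm(600, sd = 0.01), ncol = 3)
  blob2 <- sweep(matrix(rnorm(600, sd = 0.01), ncol = 3), 2, c(0.1, 0, 0), "+")
  lab <- kmeansppSplit(rbind(blob1, blob2), 2, kmeansConfig(seed = 4))
  truth <- rep(1:2, each = 200)
  agree <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_gte(agree, 0.95)
  # K equal to point count puts every point in its own cluster
  pts <- rand_cloud(5, 8)
  expect_setequal(kmeansppSplit(pts, 5, kmeansConfig(seed = 1,
                                                     min_center_sep = 1e-6)),
                  1:5)
  # determinism under a fixed seed
  expect_identical(kmeansppSplit(rbind(blob1, blob2), 2, kmeansConfig(seed = 9)),
                   kmeansppSplit(rbind(blob1, blob2), 2, kmeansConfig(seed = 9)))
})

test_that("segmentLeaves counts well-separated leaves correctly", {
  sp <- plantSpec(n_leaves = 5, outlier_count = 0, seed = 19)
  pl <- generatePlant(sp)
  lab <- pointLabels(pl$cloud)
  leaf <- plantCloud(coords(pl$cloud)[grepl("^leaf", lab), , drop = FALSE],
                     labels = lab[grepl("^leaf", lab)])
  seg <- segmentLeaves(leaf)
  sc <- leafInstanceScore(pointLabels(seg), pointLabels(leaf))
  expect_gte(sc[["recall"]], 0.8)
  expect_equal(sc[["n_true"]], 5)
  # labels partition the cloud
  expect_length(pointLabels(seg), nPoints(leaf))
})

test_that("a single leaf yields one cluster and no split", {
  sp <- plantSpec(n_leaves = 1, outlier_count = 0, seed = 23)
  pl <- generatePlant(sp)
  lab <- pointLabels(pl$cloud)
  leaf <- plantCloud(coords(pl$cloud)[lab == "leaf_1", , drop = FALSE])
  seg <- segmentLeaves(leaf)
  expect_equal(length(unique(seg@labels[seg@labels > 0])), 1)
  expect_equal(nrow(seg@kTable), 0)
})
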