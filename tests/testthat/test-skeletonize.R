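test_that("voxel partition matches brute-force floor-division binning", {
  p <- rand_cloud(1000, 1, scale = 0.1)
  L <- 0.01
  part <- partitionVoxels(p, L)
  lo <- apply(p, 2, min)
  sub <- floor(sweep(p, 2, lo) / (L / 2))
  expect_identical(part$sub_id, paste(sub[, 1], sub[, 2], sub[, 3]))
  parent <- floor(sub / 2)
  expect_identical(part$parent_id, paste(parent[, 1], parent[, 2], parent[, 3]))
  # every point in exactly one sub-cube; counts add up
  expect_equal(sum(part$sub_table$m), 1000)
})

test_that("grid arithmetic separates parent cubes and handles single points", {
  p <- rbind(c(0.001, 0.001, 0.001), c(0.015, 0.001, 0.001))
  part <- partitionVoxels(p, 0.01)
  expect_equal(length(unique(part$parent_id)), 2)
  one <- partitionVoxels(matrix(c(1, 2, 3), 1), 0.01)
  expect_equal(nrow(one$sub_table), 1)
  expect_error(partitionVoxels(matrix(numeric(0), 0, 3), 0.01), "empty")
})

test_that("sub-cube centroids are arithmetic means", {
  expect_equal(subCubeCentroid(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  sym <- rbind(c(1, 2, 3), -c(1, 2, 3))
  expect_equal(subCubeCentroid(sym), c(0, 0, 0))
  set.seed(4)
  q <- matrix(rnorm(150), 50)
  expect_equal(subCubeCentroid(q), colMeans(q), tolerance = 1e-12)
  expect_error(subCubeCentroid(q[0, ]), "empty")
})

test_that("weighted centroid equals the mean of retained union (oracle)", {
  for (seed in 1:6) {
    p <- rand_cloud(600, seed, scale = 0.08)
    part <- partitionVoxels(p, 0.01)
    wc <- weightedCentroids(part, theta = 2)
    # oracle: per parent cube, plain mean over points in sub-cubes with m > 2
    keep_sub <- part$sub_table$sub[part$sub_table$m > 2]
    sel <- part$sub_id %in% keep_sub
    f <- factor(part$parent_id[sel],
                levels = unique(part$sub_table$parent[part$sub_table$m > 2]))
    oracle <- rowsum(p[sel, , drop = FALSE], f) /
      as.integer(table(f))
    expect_equal(unname(wc$points), unname(oracle), tolerance = 1e-10)
  }
})

test_that("symmetric sub-cube occupancy yields the parent-cube center", {
  L <- 0.02
  centers <- as.matrix(expand.grid(c(L / 4, 3 * L / 4), c(L / 4, 3 * L / 4),
                                   c(L / 4, 3 * L / 4)))
  wc <- weightedCentroids(partitionVoxels(centers, L), theta = 0)
  expect_equal(nrow(wc$points), 1)
  expect_equal(drop(wc$points), unname(colMeans(centers)), tolerance = 1e-12)
})

test_that("a threshold above every count empties the skeleton", {
  p <- rand_cloud(100, 2, scale = 0.05)
  wc <- weightedCentroids(partitionVoxels(p, 0.01), theta = 1e6)
  expect_equal(nrow(wc$points), 0)
})

test_that("iterative skeleton thins monotonically and stays in bounds", {
  pl <- generatePlant(plantSpec(seed = 6))
  sk <- skeletonize(pl$cloud, n_iter = 3)
  sizes <- sk@metadata$sizes_per_iteration
  expect_true(all(diff(sizes) < 0))
  expect_lt(nPoints(sk), nPoints(pl$cloud))
  bbc <- apply(coords(pl$cloud), 2, range)
  bbs <- apply(coords(sk), 2, range)
  expect_true(all(bbs[1, ] >= bbc[1, ] - 1e-9 & bbs[2, ] <= bbc[2, ] + 1e-9))
})

test_that("skeleton of a dense cylinder hugs the true axis", {
  cl <- cylinder_cloud()
  sk <- skeletonize(cl)  # defaults: L0 = 0.01, theta = 6, three passes
  expect_equal(sk@metadata$L0, 0.01)
  expect_equal(sk@metadata$theta, 6)
  lateral <- sqrt(coords(sk)[, 1]^2 + coords(sk)[, 3]^2)
  expect_lt(max(lateral), 0.005)
})

test_that("skeletonization is translation-equivariant", {
  p <- coords(generatePlant(plantSpec(n_leaves = 3, outlier_count = 0,
                                      seed = 7))$cloud)
  shift <- c(1.234, -5.678, 9.012)
  a <- skeletonize(p, n_iter = 2)
  b <- skeletonize(sweep(p, 2, -shift), n_iter = 2)
  expect_equal(coords(a), sweep(coords(b), 2, shift), tolerance = 1e-9)
})

test_that("collapse to fewer than 2 points warns and returns the last pass", {
  p <- rand_cloud(50, 3, scale = 0.015)  # one parent cube from pass 2 on
  expect_warning(sk <- skeletonize(p, L0 = 0.01, theta = 0, n_iter = 4),
                 "collapsed")
  expect_gte(nPoints(sk), 2)
})

test_that("the geometric-centroid baseline keeps every occupied cube", {
  p <- rand_cloud(800, 12, scale = 0.06)
  geo <- skeletonize(p, n_iter = 1, method = "geometric")
  # one point per occupied parent cube, each the plain cube mean
  part <- partitionVoxels(p, 0.01)
  f <- factor(part$parent_id, levels = unique(part$parent_id))
  oracle <- rowsum(p, f) / as.integer(table(f))
  expect_equal(nPoints(geo), nlevels(f))
  ord <- order(coords(geo)[, 1], coords(geo)[, 2], coords(geo)[, 3])
  orc <- order(oracle[, 1], oracle[, 2], oracle[, 3])
  expect_equal(coords(geo)[ord, ], unname(oracle[orc, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # the density-weighted skeleton never keeps more cubes than the baseline
  den <- skeletonize(p, n_iter = 1, theta = 1)
  expect_lte(nPoints(den), nPoints(geo))
})
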