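test_that("spec validation names the offending field", {
  expect_error(plantSpec(stem_radius = -1), "stem_radius")
  expect_error(plantSpec(n_leaves = 2, leaf_attach_heights = c(0.5, 1.2)),
               "leaf_attach_heights")
  expect_error(plantSpec(n_leaves = 1, leaf_semi_axes = c(0.01, 0.02)),
               "leaf_semi_axes")
  expect_error(plantSpec(points_per_m2 = 0), "points_per_m2")
})

test_that("leafless noiseless plant is a pure cylinder with analytic truth", {
  sp <- plantSpec(n_leaves = 0, stem_curvature = 0, noise_sigma = 0,
                  outlier_count = 0, seed = 3)
  pl <- generatePlant(sp)
  expect_equal(pl$truth$true_stem_length, sp$stem_height, tolerance = 1e-6)
  expect_equal(pl$truth$true_height, sp$stem_height, tolerance = 1e-3)
  # all points at exactly stem_radius from the vertical axis
  r <- sqrt(coords(pl$cloud)[, 1]^2 + coords(pl$cloud)[, 3]^2)
  expect_lt(max(abs(r - sp$stem_radius)), 1e-12)
})

test_that("leaf areas are the analytic ellipse areas", {
  sp <- plantSpec(n_leaves = 1, leaf_semi_axes = c(0.03, 0.015), seed = 1)
  pl <- generatePlant(sp)
  expect_equal(pl$truth$true_leaf_areas, pi * 0.03 * 0.015)
  expect_equal(pl$truth$true_stem_diameter, 2 * sp$stem_radius)
})

test_that("same spec and seed give bitwise-identical clouds", {
  a <- generatePlant(plantSpec(seed = 11))
  b <- generatePlant(plantSpec(seed = 11))
  expect_identical(coords(a$cloud), coords(b$cloud))
  expect_identical(a$cloud@labels, b$cloud@labels)
  c_ <- generatePlant(plantSpec(seed = 12))
  expect_false(identical(coords(a$cloud), coords(c_$cloud)))
})

test_that("noiseless stem points lie within stem_radius of the axis polyline", {
  sp <- plantSpec(n_leaves = 4, noise_sigma = 0, outlier_count = 0, seed = 5)
  pl <- generatePlant(sp)
  stem <- coords(pl$cloud)[pl$truth$per_point_label == "stem", , drop = FALSE]
  d <- skelphen:::cpp_polyline_dist(stem, pl$truth$stem_axis_samples,
                                    sp$stem_radius, 0.001)
  expect_lte(max(d), sp$stem_radius + 1e-9)
})

test_that("convex hull area of a dense noiseless leaf approaches pi*a*b", {
  # sample one planar elliptical patch at ~5000 points and compare the area
  # of its 2D convex hull with the analytic value
  sp <- plantSpec(n_leaves = 1, leaf_semi_axes = c(0.04, 0.02),
                  noise_sigma = 0, outlier_count = 0,
                  points_per_m2 = 5000 / (pi * 0.04 * 0.02), seed = 2)
  pl <- generatePlant(sp)
  leaf <- coords(pl$cloud)[pl$truth$per_point_label == "leaf_1", , drop = FALSE]
  # petiole points are cylinder samples; keep the planar blade only
  ctr <- colMeans(leaf)
  q <- sweep(leaf, 2, ctr)
  ev <- eigen(crossprod(q), symmetric = TRUE)
  uv <- q %*% ev$vectors[, 1:2]
  hull <- chull(uv)
  hx <- uv[hull, 1]; hy <- uv[hull, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  expect_lt(abs(area - pi * 0.04 * 0.02) / (pi * 0.04 * 0.02), 0.03)
})

test_that("random specs stay inside the study conditions", {
  for (seed in 1:8) {
    sp <- randomPlantSpec(seed)
    expect_gte(sp$stem_height, 0.30); expect_lte(sp$stem_height, 0.50)
    expect_gte(sp$n_leaves, 5); expect_lte(sp$n_leaves, 10)
    expect_true(all(sp$leaf_attach_heights > 0 & sp$leaf_attach_heights < 1))
    expect_true(all(diff(sp$leaf_attach_heights) >= 0))
    expect_equal(sp$noise_sigma, 0.001)
    expect_equal(sp$outlier_count, 200L)
  }
})

test_that("fixtures round-trip through PLY + JSON", {
  sp <- plantSpec(n_leaves = 3, points_per_m2 = 3e4, outlier_count = 10,
                  seed = 7)
  pl <- generatePlant(sp)
  dir <- withr::local_tempdir()
  writeFixture(pl$cloud, pl$truth, dir)
  back <- readFixture(dir)
  expect_equal(coords(back$cloud), coords(pl$cloud), tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_identical(pointLabels(back$cloud), pointLabels(pl$cloud))
  expect_length(back$truth$true_leaf_areas, 3)
  expect_equal(back$truth$true_height, pl$truth$true_height)
})
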