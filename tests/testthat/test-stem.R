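test_that("MST handles the smallest cases and collinear points", {
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  g <- buildMST(two)
  expect_equal(nrow(g@edges), 1)
  expect_equal(g@weights, 1)
  tri <- rbind(c(0, 0, 0), c(0, 0.1, 0), c(0, 0.3, 0))
  g <- buildMST(tri)
  keys <- apply(g@edges, 1, function(e) paste(sort(e), collapse = "-"))
  expect_setequal(keys, c("1-2", "2-3"))  # never the long chord 1-3
  expect_error(buildMST(two[1, , drop = FALSE]), "at least 2")
})

test_that("MST weight matches an independent Prim implementation", {
  for (seed in c(1, 2, 3)) {
    n <- c(50, 200, 500)[seed]
    p <- rand_cloud(n, seed)
    g <- buildMST(p)
    expect_equal(sum(g@weights), oracle_prim_weight(p), tolerance = 1e-9)
  }
})

test_that("kNN-graph MST fast path agrees with the exact tree", {
  p <- rand_cloud(300, 9)
  exact <- buildMST(p)
  fast <- buildMST(p, method = "knn", k = 10)
  expect_equal(sum(fast@weights), sum(exact@weights), tolerance = 1e-9)
})

test_that("MST weight matches exhaustive enumeration for small n", {
  for (seed in 1:3) {
    p <- rand_cloud(6, seed)
    g <- buildMST(p)
    expect_equal(sum(g@weights), oracle_exhaustive_mst_weight(p),
                 tolerance = 1e-9)
  }
})

test_that("node classes follow the degree histogram", {
  # 5-node path
  path5 <- cbind(seq(0, 0.4, 0.1), 0, 0)
  cls <- classifyNodes(buildMST(path5))
  expect_equal(sum(cls == "TIP"), 2)
  expect_equal(sum(cls == "INTERNAL"), 3)
  # star K_{1,3}
  star <- rbind(c(0, 0, 0), c(1, 0, 0), c(-0.5, 0.9, 0), c(-0.5, -0.9, 0))
  cls <- classifyNodes(buildMST(star))
  expect_equal(cls[1], "JUNCTION")
  expect_equal(sum(cls == "TIP"), 3)
  # random tree: classes equal an independent degree count
  p <- rand_cloud(50, 4)
  g <- buildMST(p)
  deg <- tabulate(c(g@edges), 50)
  expect_identical(g@nodeClass,
                   c("TIP", "INTERNAL", "JUNCTION")[pmin(pmax(deg, 1), 3)])
})

test_that("principal direction matches a power-iteration oracle", {
  yline <- cbind(0, seq(0, 1, 0.01), 0)
  expect_equal(principalDirection(yline)$direction, c(0, 1, 0),
               tolerance = 1e-9)
  # descending parameterization still yields +Y after the sign flip
  expect_equal(principalDirection(yline[101:1, ])$direction, c(0, 1, 0),
               tolerance = 1e-9)
  set.seed(8)
  aniso <- cbind(rnorm(400, sd = 10), rnorm(400, sd = 2), rnorm(400, sd = 1))
  d <- principalDirection(aniso)$direction
  o <- oracle_power_direction(aniso)
  ang <- acos(min(1, abs(sum(d * o))))
  expect_lt(ang, 2 * pi / 180)
  expect_error(principalDirection(yline[c(1, 1, 1), ]), "identical")
})

test_that("highest junction near the line is selected; off-line excluded", {
  # vertical chain with on-line junctions at 0.1 m and 0.3 m
  mk <- function(y, x = 0, z = 0) c(x, y, z)
  pts <- rbind(mk(0), mk(0.1), mk(0.2), mk(0.3), mk(0.4),
               mk(0.1, 0.05), mk(0.105, 0.1),     # low branch
               mk(0.3, 0.05), mk(0.305, 0.1))    # high branch
  g <- buildMST(pts)
  line <- list(direction = c(0, 1, 0), anchor = c(0, 0, 0))
  jn <- selectHighestJunction(g, line, radius = 0.02)
  expect_equal(g@nodes[jn, 2], 0.3)
  expect_error(selectHighestJunction(g, list(direction = c(0, 1, 0),
                                             anchor = c(5, 0, 0)), 0.02),
               "no skeleton node")
})

test_that("a junction 3 cm off the line is excluded by the 2 cm gate", {
  mk <- function(y, x = 0, z = 0) c(x, y, z)
  pts <- rbind(mk(0), mk(0.1), mk(0.2), mk(0.3), mk(0.4),
               mk(0.1, 0.05), mk(0.105, 0.1),            # on-line junction at 0.1
               c(0.03, 0.35, 0), c(0.06, 0.33, 0), c(0.06, 0.37, 0))
  g <- buildMST(pts)
  expect_true("JUNCTION" %in% g@nodeClass[8])  # the off-line node branches
  line <- list(direction = c(0, 1, 0), anchor = c(0, 0, 0))
  jn <- selectHighestJunction(g, line, radius = 0.02)
  expect_equal(g@nodes[jn, 2], 0.1)  # the off-line 0.35 m junction is skipped
})

test_that("unbranched plants fall back to the highest near-line node", {
  chain <- cbind(0, seq(0, 0.4, 0.1), 0)
  g <- buildMST(chain)
  line <- list(direction = c(0, 1, 0), anchor = c(0, 0, 0))
  expect_warning(jf <- selectHighestJunction(g, line, radius = 0.02),
                 "no junction")
  expect_equal(g@nodes[jf, 2], 0.4)
})

test_that("root node is the lowest near-line node, rejecting off-axis tips", {
  pts <- rbind(c(0, 0, 0), c(0, 0.1, 0), c(0, 0.2, 0),
               c(0.05, -0.05, 0))  # low-hanging leaf tip 5 cm off-line
  g <- buildMST(pts)
  line <- list(direction = c(0, 1, 0), anchor = c(0, 0.1, 0))
  rt <- rootNode(g, line, radius = 0.02)
  expect_equal(unname(g@nodes[rt, ]), c(0, 0, 0))
  expect_error(rootNode(g, list(direction = c(0, 1, 0), anchor = c(9, 0, 0)),
                        0.02), "no skeleton node")
})

test_that("Dijkstra tree path equals the unique DFS path", {
  p5 <- cbind(seq(0, 0.4, 0.1), 0, 0)
  g <- buildMST(p5)
  expect_identical(treePath(g, 3, 3), 3L)
  expect_identical(treePath(g, 1, 5), 1:5)
  for (seed in 1:10) {
    p <- rand_cloud(60, seed + 100)
    g <- buildMST(p)
    src <- (seed * 7) %% 60 + 1
    dst <- (seed * 13) %% 60 + 1
    expect_identical(treePath(g, src, dst),
                     oracle_dfs_path(g@edges, 60, src, dst))
  }
})

test_that("spline smoothing preserves straight lines and circular arcs", {
  line3 <- rbind(c(0, 0, 0), c(0, 0.2, 0), c(0, 0.4, 0))
  cv <- smoothCurve(line3, step = 0.001)
  expect_equal(stemLength(cv), 0.4, tolerance = 1e-6)
  expect_lt(max(abs(coords(cv)[, c(1, 3)])), 1e-9)
  # 2-point path degrades to a straight segment
  cv2 <- smoothCurve(rbind(c(0, 0, 0), c(0, 0.4, 0)), step = 0.001)
  expect_equal(stemLength(cv2), 0.4, tolerance = 1e-9)
  # quarter circle of radius 0.1: arc length within 1% of pi*r/2
  cv3 <- smoothCurve(quarter_circle(), step = 0.001)
  expect_lt(abs(stemLength(cv3) - pi * 0.1 / 2) / (pi * 0.1 / 2), 0.01)
  expect_warning(smoothCurve(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0.1, 0))),
                 "duplicate")
})

test_that("stem labeling is exact on cylinders and monotone in radius", {
  cl <- cylinder_cloud(radius = 0.002, height = 0.3, n = 5000)
  axis <- cbind(0, seq(0, 0.3, 0.001), 0)
  curve <- smoothCurve(axis[c(1, 150, 301), ], step = 0.001)
  mask3 <- labelStem(plantCloud(cl), curve, 0.003)
  expect_true(all(mask3))  # cylinder radius 2 mm inside 3 mm search
  far <- plantCloud(rbind(cl[1:10, ], c(0.02, 0.15, 0)))
  maskf <- labelStem(far, curve, 0.002)
  expect_false(maskf[11])
  # monotone: r1 < r2 => stem(r1) subset of stem(r2)
  p <- rand_cloud(500, 11, scale = 0.05)
  m1 <- labelStem(plantCloud(p), curve, 0.004)
  m2 <- labelStem(plantCloud(p), curve, 0.012)
  expect_true(all(m2[m1]))
})

test_that("stem labeling on a default synthetic plant reaches F1 >= 0.90", {
  sp <- plantSpec(seed = 21)
  pl <- generatePlant(sp)
  f <- sorFilter(pl$cloud, sorConfig())
  sk <- skeletonize(f$cloud, n_iter = 2)
  g <- buildMST(coords(sk))
  line <- principalDirection(coords(sk))
  path <- treePath(g, selectHighestJunction(g, line, 0.02),
                   rootNode(g, line, 0.02))
  pp <- skelphen:::.anchor_path_base(g@nodes[rev(path), , drop = FALSE],
                                     min(coords(f$cloud)[, 2]))
  curve <- smoothCurve(pp, 0.001)
  mask <- labelStem(f$cloud, curve, 2 * sp$stem_radius + 0.003)
  s <- stemF1(mask, pointLabels(f$cloud))
  expect_gte(s[["f1"]], 0.90)
})
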