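test_that("three points make one triangle; tiny inputs error", {
  tri <- triangulateLeaf(rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0)))
  expect_equal(nrow(tri$triangles), 1)
  expect_equal(leafArea(tri), 0.01 * 0.01 / 2, tolerance = 1e-12)
  expect_error(triangulateLeaf(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
})

test_that("a planar grid triangulates to a disk-like patch (Euler check)", {
  g <- as.matrix(expand.grid(seq(0, 0.02, 0.002), seq(0, 0.02, 0.002)))
  mesh <- triangulateLeaf(cbind(g[, 1], 0, g[, 2]), mu = 1.8)
  V <- length(unique(as.vector(mesh$triangles)))
  ekeys <- unique(paste(skelphen:::.mesh_edges(mesh$triangles)[, 1],
                        skelphen:::.mesh_edges(mesh$triangles)[, 2]))
  E <- length(ekeys)
  F_ <- nrow(mesh$triangles)
  expect_equal(V - E + F_, 1)  # disk topology
  rings <- boundaryRings(mesh)
  expect_length(rings$rings, 1)
})

test_that("a removed interior block creates a detectable hole ring", {
  xs <- seq(0, 0.02, 0.002)
  g <- as.matrix(expand.grid(xs, xs))
  drop_ <- g[, 1] >= 0.008 & g[, 1] <= 0.012 & g[, 2] >= 0.008 & g[, 2] <= 0.012
  holey <- g[!drop_, ]
  mesh <- triangulateLeaf(cbind(holey[, 1], 0, holey[, 2]), mu = 1.8)
  rings <- boundaryRings(mesh)
  expect_gte(length(rings$rings), 2)
  # outer ring has the larger perimeter
  perim <- function(r) {
    v <- mesh$vertices[c(r, r[1]), ]
    sum(sqrt(rowSums(diff(v)^2)))
  }
  ps <- vapply(rings$rings, perim, numeric(1))
  expect_equal(rings$outer_ring_id, which.max(ps))
  # hole repair removes every internal ring
  filled <- fillHoles(mesh, rings)
  rings2 <- boundaryRings(filled)
  expect_length(rings2$rings, 1)
})

test_that("annulus sampling yields two rings, larger labeled outer", {
  set.seed(6)
  n <- 1200
  r <- sqrt(runif(n, 0.015^2, 0.03^2))
  t <- runif(n, 0, 2 * pi)
  ann <- cbind(r * cos(t), 0, r * sin(t))
  mesh <- triangulateLeaf(ann, mu = 2.5, max_edge = 0.01)
  rings <- boundaryRings(mesh)
  expect_gte(length(rings$rings), 2)
  outer <- rings$rings[[rings$outer_ring_id]]
  rad_out <- mean(sqrt(rowSums(mesh$vertices[outer, c(1, 3)]^2)))
  expect_gt(rad_out, 0.025)  # the outer ring sits at the outer radius
})

test_that("hole filling adds n-2 triangles per ring (ear count)", {
  # hand-built hexagonal annulus band: inner ring = 6-vertex hole
  band_mesh <- function(k) {
    t_ <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
    verts <- rbind(cbind(0.005 * cos(t_), 0, 0.005 * sin(t_)),
                   cbind(0.010 * cos(t_), 0, 0.010 * sin(t_)))
    tris <- do.call(rbind, lapply(seq_len(k), function(i) {
      j <- i %% k + 1
      rbind(c(i, k + i, k + j), c(i, k + j, j))
    }))
    structure(list(vertices = verts, triangles = tris), class = "LeafMesh")
  }
  for (k in c(3, 4, 6)) {   # triangular, square and hexagonal holes
    mesh <- band_mesh(k)
    rings <- boundaryRings(mesh)
    holes <- setdiff(seq_along(rings$rings), rings$outer_ring_id)
    expect_length(holes, 1)
    expect_length(rings$rings[[holes]], k)
    filled <- fillHoles(mesh, rings)
    expect_equal(nrow(filled$triangles), nrow(mesh$triangles) + k - 2)
    expect_length(boundaryRings(filled)$rings, 1)
  }
})

test_that("mesh area approaches the analytic disk area after repair", {
  set.seed(9)
  n <- 4000
  rr <- sqrt(runif(n)) * 0.03
  th <- runif(n, 0, 2 * pi)
  disk <- cbind(rr * cos(th), 0, rr * sin(th))
  mesh <- fillHoles(triangulateLeaf(disk))
  a <- leafArea(mesh)
  expect_lt(abs(a - pi * 0.03^2) / (pi * 0.03^2), 0.05)
  # double-sided flag halves exactly
  expect_equal(leafArea(mesh, double_sided = TRUE), a / 2)
})

test_that("closed meshes report zero boundary rings", {
  # a tetrahedron is closed: every edge bounds two triangles
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tris <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  mesh <- structure(list(vertices = verts, triangles = tris),
                    class = "LeafMesh")
  rings <- boundaryRings(mesh)
  expect_length(rings$rings, 0)
  expect_identical(fillHoles(mesh, rings), mesh)
})
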