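# Leaf surface meshing. Leaves are near-planar patches, so each leaf cloud is
# projected onto its PCA plane, triangulated with a Delaunay triangulation
# (own Bowyer-Watson, no external geometry dependency) and pruned of
# triangles whose edges exceed a spacing-scaled search radius. Pruning
# introduces interior holes exactly where the sampling is sparse; these are
# detected as boundary rings and repaired by iterative point linking before
# the triangle areas are summed.

# --- 2D Delaunay (Bowyer-Watson, vectorized per insertion) -----------------

.circumcircle <- function(P, tri) {
  ax <- P[tri[, 1], 1]; ay <- P[tri[, 1], 2]
  bx <- P[tri[, 2], 1]; by <- P[tri[, 2], 2]
  cx <- P[tri[, 3], 1]; cy <- P[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  bad <- !is.finite(ux) | !is.finite(uy) | abs(d) < 1e-300
  ux[bad] <- Inf; uy[bad] <- Inf; r2[bad] <- -Inf  # degenerate: never "bad"
  cbind(ux, uy, r2)
}

# Delaunay triangulation of 2D points; returns an m x 3 index matrix.
# A deterministic sub-micron jitter breaks co-circular degeneracies
# (regular grids); it is far below any meaningful point spacing.
.delaunay2d <- function(uv) {
  n <- nrow(uv)
  if (n < 3) stop("triangulation needs at least 3 points")
  span <- max(apply(uv, 2, function(v) diff(range(v))), 1e-12)
  h <- (seq_len(n) * 2654435761) %% 8192
  uv <- uv + span * 1e-9 * cbind(h / 8192 - 0.5,
                                 ((h * 7919) %% 8192) / 8192 - 0.5)
  lo <- apply(uv, 2, min); hi <- apply(uv, 2, max)
  ctr <- (lo + hi) / 2
  big <- 10 * max(hi - lo, 1e-9)
  P <- rbind(uv,
             c(ctr[1] - 2 * big, ctr[2] - big),
             c(ctr[1] + 2 * big, ctr[2] - big),
             c(ctr[1], ctr[2] + 2 * big))
  tri <- matrix(c(n + 1L, n + 2L, n + 3L), 1, 3)
  cc <- .circumcircle(P, tri)
  for (i in seq_len(n)) {
    d2 <- (cc[, 1] - P[i, 1])^2 + (cc[, 2] - P[i, 2])^2
    bad <- which(d2 < cc[, 3])
    if (!length(bad)) next  # cannot happen inside the super-triangle, guard
    bt <- tri[bad, , drop = FALSE]
    e <- rbind(bt[, c(1, 2)], bt[, c(2, 3)], bt[, c(3, 1)])
    ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    keep_e <- !(ek %in% ek[duplicated(ek)])
    poly <- e[keep_e, , drop = FALSE]
    tri <- tri[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(poly, i)
    tri <- rbind(tri, newt)
    cc <- rbind(cc, .circumcircle(P, newt))
  }
  tri <- tri[apply(tri <= n, 1, all), , drop = FALSE]
  storage.mode(tri) <- "integer"
  unname(tri)
}

#' Triangulate a leaf point cloud into a surface mesh
#'
#' Projects the points onto their PCA plane, Delaunay-triangulates the
#' projection, and removes triangles having any edge longer than
#' \code{min(mu * median 4th-neighbour spacing, max_edge)}; sparse spots
#' therefore become interior holes, to be repaired via
#' \code{\link{boundaryRings}} and \code{\link{fillHoles}}. Triangle areas
#' are always computed from the original 3D vertices, so mild leaf curvature
#' is preserved.
#'
#' @param leaf_cloud a \linkS4class{PlantCloud} or n x 3 matrix (n >= 3)
#' @param mu spacing multiplier for the edge-length cap
#' @param max_edge absolute edge-length cap (m)
#' @return list of class \code{"LeafMesh"}: \code{vertices} (n x 3),
#'   \code{triangles} (m x 3 indices)
#' @export
triangulateLeaf <- function(leaf_cloud, mu = 2.5, max_edge = 0.02) {
  p <- if (is(leaf_cloud, "PlantCloud")) coords(leaf_cloud) else
    as.matrix(leaf_cloud)
  n <- nrow(p)
  if (n < 3) stop("triangulation needs at least 3 points")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  ev <- eigen(crossprod(q), symmetric = TRUE)
  uv <- q %*% ev$vectors[, 1:2]
  tri <- if (n == 3) matrix(1:3, 1) else .delaunay2d(uv)
  if (n > 3) {
    # 4th-neighbour distance: tracks the typical Delaunay edge length for
    # both lattice and Poisson-like sampling (1st-NN underestimates it)
    k <- min(5L, n)
    spacing <- stats::median(cpp_knn(p, p, k)$dist[, k])
    cap <- min(mu * spacing, max_edge)
    el <- function(a, b) sqrt(rowSums((p[a, , drop = FALSE] -
                                       p[b, , drop = FALSE])^2))
    maxedge <- pmax(el(tri[, 1], tri[, 2]), el(tri[, 2], tri[, 3]),
                    el(tri[, 3], tri[, 1]))
    tri <- tri[maxedge <= cap, , drop = FALSE]
  }
  if (nrow(tri) == 0)
    stop("no mutually connectable points at this edge-length cap")
  structure(list(vertices = p, triangles = tri), class = "LeafMesh")
}

# Mesh-prep downsample: bin the points on a 2D grid in their PCA plane and
# average the 3D coordinates per occupied cell. Unlike a 3D voxel grid this
# cannot split a noisy slab into parallel layers: each cell yields one point
# with the surface noise averaged out.
.planar_downsample <- function(p, cell) {
  p <- as.matrix(p)
  if (nrow(p) < 4) return(p)
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  ev <- eigen(crossprod(q), symmetric = TRUE)
  uv <- q %*% ev$vectors[, 1:2]
  key <- paste(floor(uv[, 1] / cell), floor(uv[, 2] / cell))
  f <- factor(key, levels = unique(key))
  unname(rowsum(p, f) / as.integer(table(f)))
}

# canonical edge keys of a triangle matrix
.mesh_edges <- function(tri) {
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Boundary rings of a triangle mesh
#'
#' Boundary edges (edges incident to exactly one triangle) are linked into
#' closed loops; the ring with the greatest total edge length is the outer
#' boundary, every other ring is an interior hole.
#'
#' @param mesh a \code{"LeafMesh"}
#' @return list with \code{rings} (list of ordered vertex-index loops),
#'   \code{outer_ring_id} (index into \code{rings}; 0 if the mesh is closed)
#' @export
boundaryRings <- function(mesh) {
  stopifnot(inherits(mesh, "LeafMesh"))
  e <- .mesh_edges(mesh$triangles)
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1]
  if (!length(bkey)) return(list(rings = list(), outer_ring_id = 0L))
  be <- e[match(bkey, key), , drop = FALSE]
  # vertex -> incident boundary edges
  used <- rep(FALSE, nrow(be))
  inc <- split(rep(seq_len(nrow(be)), 2), c(be[, 1], be[, 2]))
  rings <- list()
  for (start in seq_len(nrow(be))) {
    if (used[start]) next
    ring <- c(be[start, 1], be[start, 2])
    used[start] <- TRUE
    repeat {
      v <- ring[length(ring)]
      cand <- inc[[as.character(v)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) {
        if (v == ring[1]) break  # closed
        stop("non-closable boundary chain at vertex ", v)
      }
      eid <- cand[1]
      used[eid] <- TRUE
      nxt <- if (be[eid, 1] == v) be[eid, 2] else be[eid, 1]
      if (nxt == ring[1]) break
      ring <- c(ring, nxt)
    }
    rings[[length(rings) + 1]] <- ring
  }
  perim <- vapply(rings, function(r) {
    v <- mesh$vertices[c(r, r[1]), , drop = FALSE]
    sum(sqrt(rowSums(diff(v)^2)))
  }, numeric(1))
  list(rings = rings, outer_ring_id = which.max(perim))
}

# triangulate one ring (vertex loop) by iterative point linking: repeatedly
# connect the vertex with the smallest interior angle to its two neighbours
.fill_ring <- function(vertices, ring) {
  tris <- matrix(integer(0), 0, 3)
  loop <- ring
  # 2D frame of the ring's best-fit plane for angle/orientation tests
  while (length(loop) > 3) {
    P <- vertices[loop, , drop = FALSE]
    m <- length(loop)
    prv <- c(m, seq_len(m - 1)); nxt <- c(2:m, 1)
    v1 <- P[prv, , drop = FALSE] - P
    v2 <- P[nxt, , drop = FALSE] - P
    n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
    bad <- n1 == 0 | n2 == 0
    if (any(bad)) return(list(tris = tris, fallback = TRUE, loop = loop))
    ang <- acos(pmin(1, pmax(-1, rowSums(v1 * v2) / (n1 * n2))))
    i <- which.min(ang)
    tris <- rbind(tris, loop[c(prv[i], i, nxt[i])])
    loop <- loop[-i]
  }
  tris <- rbind(tris, loop)
  list(tris = tris, fallback = FALSE)
}

#' Repair interior holes of a leaf mesh
#'
#' Every ring except the outer boundary is filled by iterative point
#' linking (ear-style: the boundary vertex with the smallest interior angle
#' is connected to its neighbours until the ring reduces to a triangle).
#' Degenerate rings fall back to a centroid fan with a warning. The outer
#' ring is left untouched.
#'
#' @param mesh a \code{"LeafMesh"}
#' @param rings a \code{\link{boundaryRings}} result (recomputed if missing)
#' @return the repaired \code{"LeafMesh"}
#' @export
fillHoles <- function(mesh, rings = NULL) {
  stopifnot(inherits(mesh, "LeafMesh"))
  if (is.null(rings)) rings <- boundaryRings(mesh)
  if (length(rings$rings) <= 1) return(mesh)
  holes <- setdiff(seq_along(rings$rings), rings$outer_ring_id)
  for (h in holes) {
    r <- rings$rings[[h]]
    if (length(r) < 3) next
    res <- .fill_ring(mesh$vertices, r)
    if (res$fallback) {
      warning("degenerate hole ring; filled with a centroid fan")
      ctr <- colMeans(mesh$vertices[res$loop, , drop = FALSE])
      mesh$vertices <- rbind(mesh$vertices, ctr)
      ci <- nrow(mesh$vertices)
      lp <- res$loop
      fan <- cbind(lp, c(lp[-1], lp[1]), ci)
      mesh$triangles <- rbind(mesh$triangles, res$tris, fan)
    } else {
      mesh$triangles <- rbind(mesh$triangles, res$tris)
    }
  }
  storage.mode(mesh$triangles) <- "integer"
  mesh
}

#' Mesh surface area of a leaf
#'
#' Sum of triangle areas; with \code{double_sided = TRUE} the sum is halved,
#' for clouds in which registration sampled both faces of each blade.
#' Single-surface clouds (the synthetic generator's case) must not be halved.
#'
#' @param mesh a \code{"LeafMesh"} (hole-repaired)
#' @param double_sided halve the summed area
#' @return area in square meters
#' @export
leafArea <- function(mesh, double_sided = FALSE) {
  stopifnot(inherits(mesh, "LeafMesh"))
  tri <- mesh$triangles
  if (!nrow(tri)) return(0)
  a <- mesh$vertices[tri[, 1], , drop = FALSE]
  b <- mesh$vertices[tri[, 2], , drop = FALSE]
  c_ <- mesh$vertices[tri[, 3], , drop = FALSE]
  cr <- .cross(b - a, c_ - a)
  area <- sum(sqrt(rowSums(cr^2))) / 2
  if (double_sided) area / 2 else area
}
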