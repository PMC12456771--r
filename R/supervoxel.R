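# Supervoxel over-segmentation (VCCS-style seeded flow clustering in a
# 37-dimensional feature space: curvature, XYZ, 33-bin FPFH) and the LCCP
# convexity merge that turns supervoxels into coarse leaf clusters.

#' Supervoxel (VCCS) configuration
#'
#' Defaults: voxel resolution 8 mm, seed
#' resolution 10 mm, weights (curvature, spatial, geometric) = (0.2, 0.4, 1).
#'
#' @param R_voxel voxel octree resolution (m)
#' @param R_seed seed grid resolution (m), \code{R_seed >= R_voxel}
#' @param w_c,w_s,w_n non-negative weights for curvature, spatial distance
#'   and FPFH (histogram-intersection) distance
#' @param max_rounds flow-iteration cap
#' @return list of class \code{"VCCSConfig"}
#' @export
vccsConfig <- function(R_voxel = 0.008, R_seed = 0.01, w_c = 0.2, w_s = 0.4,
                       w_n = 1, max_rounds = 10L) {
  if (R_voxel <= 0 || R_seed < R_voxel)
    stop("need R_seed >= R_voxel > 0")
  if (any(c(w_c, w_s, w_n) < 0)) stop("weights must be >= 0")
  structure(list(R_voxel = R_voxel, R_seed = R_seed, w_c = w_c, w_s = w_s,
                 w_n = w_n, max_rounds = as.integer(max_rounds)),
            class = "VCCSConfig")
}

#' Supervoxel similarity distance
#'
#' \deqn{D = w_c D_c^2 / c_{max}^2 + w_s D_s^2 / (3 R_{seed}^2) + w_n D_n^2}
#' with \eqn{D_c} the curvature difference, \eqn{D_s} the Euclidean centroid
#' distance, and \eqn{D_n} the histogram-intersection-kernel distance between
#' FPFH descriptors.
#'
#' @param D_c,D_s,D_n the three component distances
#' @param cfg a \code{\link{vccsConfig}}
#' @param c_max maximal curvature in the competing neighbourhood (normalizer)
#' @return the scalar similarity distance
#' @export
vccsDistance <- function(D_c, D_s, D_n, cfg, c_max) {
  c2 <- max(c_max, 1e-9)^2
  cfg$w_c * D_c^2 / c2 + cfg$w_s * D_s^2 / (3 * cfg$R_seed^2) + cfg$w_n * D_n^2
}

# histogram-intersection-kernel distance between block-normalized FPFH rows
# (each sums to 300): 1 - sum(min)/300, in [0, 1]
.hik_dist <- function(a, b) 1 - sum(pmin(a, b)) / 300

# voxelize a cloud on an R_voxel grid anchored at the min corner; returns
# integer voxel coords, centroids and the per-point voxel id
.voxelize <- function(p, R) {
  lo <- apply(p, 2, min)
  iv <- floor(sweep(p, 2, lo) / R)
  key <- paste(iv[, 1], iv[, 2], iv[, 3])
  lev <- unique(key)
  f <- factor(key, levels = lev)
  cnt <- as.integer(table(f))
  cent <- rowsum(p, f) / cnt
  ik <- do.call(rbind, strsplit(lev, " "))
  storage.mode(ik) <- "integer"
  list(coords = ik, centroid = unname(cent), count = cnt,
       point_voxel = as.integer(f), lo = lo, R = R)
}

# 26-connectivity adjacency list between occupied voxels
.voxel_adjacency <- function(coords) {
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  lookup <- seq_len(nrow(coords))
  names(lookup) <- key
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  adj <- vector("list", nrow(coords))
  for (r in seq_len(nrow(offs))) {
    nk <- paste(coords[, 1] + offs[r, 1], coords[, 2] + offs[r, 2],
                coords[, 3] + offs[r, 3])
    hit <- lookup[nk]
    ok <- !is.na(hit)
    if (any(ok))
      for (i in which(ok)) adj[[i]] <- c(adj[[i]], unname(hit[i]))
  }
  adj
}

#' VCCS supervoxel over-segmentation
#'
#' Voxelizes the cloud at \code{R_voxel}, computes per-voxel normals,
#' curvature and FPFH, places seeds on an \code{R_seed} grid (culling seeds
#' with fewer than 3 occupied voxel neighbours), and grows supervoxels by
#' breadth-first flow restricted to voxel-grid connectivity, assigning each
#' voxel to the seed minimizing the similarity distance
#' (\code{\link{vccsDistance}}). Flow repeats with re-estimated supervoxel
#' centers until labels stabilize or \code{max_rounds} is reached. Voxels in
#' connected components that contain no seed become their own supervoxels so
#' the result is a partition of all occupied voxels.
#'
#' @param cloud a \linkS4class{PlantCloud} or n x 3 matrix
#' @param cfg a \code{\link{vccsConfig}}
#' @param fpfh_radius FPFH neighbourhood radius (default \code{2 * R_voxel})
#' @return list of class \code{"Supervoxels"}: per-point supervoxel id
#'   \code{point_label}, per-voxel id \code{voxel_label}, supervoxel table
#'   (\code{centroid}, \code{normal}, \code{curvature}, \code{fpfh},
#'   \code{size} in points), and the symmetric supervoxel \code{adjacency}.
#' @export
vccsSupervoxels <- function(cloud, cfg = vccsConfig(),
                            fpfh_radius = 2 * cfg$R_voxel) {
  p <- if (is(cloud, "PlantCloud")) coords(cloud) else as.matrix(cloud)
  if (nrow(p) == 0) stop("empty cloud")
  vox <- .voxelize(p, cfg$R_voxel)
  nv <- nrow(vox$centroid)
  k_nrm <- min(10L, nv)
  nc <- if (nv >= 4) normalsCurvature(vox$centroid, k = k_nrm) else
    list(normals = matrix(rep(c(0, 1, 0), each = nv), nv, 3),
         curvature = numeric(nv))
  # consistent hemisphere for convexity tests: blades face upward, so orient
  # normals to +Y (centroid-based orientation flips under-centroid leaves
  # downward and turns leaf-leaf valleys into false convex contacts)
  flip <- nc$normals[, 2] < 0
  nc$normals[flip, ] <- -nc$normals[flip, , drop = FALSE]
  fh <- if (nv >= 2) fpfh(vox$centroid, nc$normals, fpfh_radius) else
    matrix(0, nv, 33)
  adj <- .voxel_adjacency(vox$coords)
  # neighbourhood curvature normalizer
  c_max <- vapply(seq_len(nv), function(i)
    max(nc$curvature[c(i, adj[[i]])]), numeric(1))

  ## seeds: one per occupied R_seed cell (voxel nearest the cell center),
  ## culled when fewer than 3 occupied voxel neighbours
  cell <- floor(sweep(vox$centroid, 2, vox$lo) / cfg$R_seed)
  ckey <- paste(cell[, 1], cell[, 2], cell[, 3])
  seeds <- vapply(split(seq_len(nv), ckey), function(members) {
    ctr <- vox$lo + (cell[members[1], ] + 0.5) * cfg$R_seed
    d2 <- rowSums(sweep(vox$centroid[members, , drop = FALSE], 2, ctr)^2)
    members[which.min(d2)]
  }, integer(1))
  seeds <- unname(sort(seeds))
  seeds <- seeds[vapply(seeds, function(s) length(adj[[s]]), 0L) >= 3]
  if (!length(seeds)) {
    if (nv <= 3) seeds <- 1L
    else stop("no supervoxel seeds survive culling; use a smaller R_seed")
  }
  ns <- length(seeds)

  sv_centroid <- vox$centroid[seeds, , drop = FALSE]
  sv_normal <- nc$normals[seeds, , drop = FALSE]
  sv_curv <- nc$curvature[seeds]
  sv_fpfh <- fh[seeds, , drop = FALSE]

  dist_to <- function(vi, s) {
    D_c <- abs(nc$curvature[vi] - sv_curv[s])
    D_s <- sqrt(sum((vox$centroid[vi, ] - sv_centroid[s, ])^2))
    D_n <- .hik_dist(fh[vi, ], sv_fpfh[s, ])
    vccsDistance(D_c, D_s, D_n, cfg, c_max[vi])
  }

  label <- integer(nv)
  for (round in seq_len(cfg$max_rounds)) {
    newlab <- integer(nv)
    best <- rep(Inf, nv)
    queue <- seeds
    for (s in seq_len(ns)) {
      vi <- seeds[s]
      newlab[vi] <- s
      best[vi] <- dist_to(vi, s)
    }
    head_ <- 1L
    while (head_ <= length(queue)) {
      vi <- queue[head_]; head_ <- head_ + 1L
      s <- newlab[vi]
      for (nb in adj[[vi]]) {
        d <- dist_to(nb, s)
        if (d < best[nb]) {
          best[nb] <- d
          if (newlab[nb] != s) { newlab[nb] <- s; queue <- c(queue, nb) }
        }
      }
    }
    if (identical(newlab, label)) break
    label <- newlab
    # re-estimate supervoxel centers in feature space
    for (s in seq_len(ns)) {
      members <- which(label == s)
      if (!length(members)) next
      sv_centroid[s, ] <- colMeans(vox$centroid[members, , drop = FALSE])
      nm <- colMeans(nc$normals[members, , drop = FALSE])
      nrmlen <- sqrt(sum(nm^2))
      if (nrmlen > 0) sv_normal[s, ] <- nm / nrmlen
      sv_curv[s] <- mean(nc$curvature[members])
      hb <- colMeans(fh[members, , drop = FALSE])
      sv_fpfh[s, ] <- hb
    }
  }

  ## seedless connected components become their own supervoxels
  if (any(label == 0)) {
    un <- which(label == 0)
    while (length(un)) {
      comp <- un[1]; frontier <- comp
      while (length(frontier)) {
        nxt <- setdiff(unlist(adj[frontier]), comp)
        nxt <- nxt[label[nxt] == 0 & !(nxt %in% comp)]
        comp <- c(comp, nxt); frontier <- nxt
      }
      ns <- ns + 1L
      label[comp] <- ns
      sv_centroid <- rbind(sv_centroid,
                           colMeans(vox$centroid[comp, , drop = FALSE]))
      nm <- colMeans(nc$normals[comp, , drop = FALSE])
      nrmlen <- sqrt(sum(nm^2)); if (nrmlen == 0) nrmlen <- 1
      sv_normal <- rbind(sv_normal, nm / nrmlen)
      sv_curv <- c(sv_curv, mean(nc$curvature[comp]))
      sv_fpfh <- rbind(sv_fpfh, colMeans(fh[comp, , drop = FALSE]))
      un <- un[!(un %in% comp)]
    }
  }

  ## supervoxel adjacency from voxel 26-connectivity across labels
  pair <- unique(do.call(rbind, lapply(seq_len(nv), function(i) {
    nb <- adj[[i]]
    if (!length(nb)) return(NULL)
    o <- cbind(label[i], label[nb])
    o[o[, 1] != o[, 2], , drop = FALSE]
  })))
  sv_adj <- vector("list", ns)
  if (!is.null(pair) && nrow(pair))
    for (r in seq_len(nrow(pair)))
      sv_adj[[pair[r, 1]]] <- sort(unique(c(sv_adj[[pair[r, 1]]], pair[r, 2])))

  point_label <- label[vox$point_voxel]
  size <- tabulate(point_label, nbins = ns)
  structure(list(point_label = point_label, voxel_label = label,
                 centroid = sv_centroid, normal = sv_normal,
                 curvature = sv_curv, fpfh = sv_fpfh, size = size,
                 adjacency = sv_adj, voxels = vox, n = ns),
            class = "Supervoxels")
}
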