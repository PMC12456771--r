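# Density-weighted voxel-centroid skeletonization. A parent grid of edge L is
# anchored at the cloud's minimum corner; each parent cube splits into eight
# half-edge sub-cubes; sub-cubes with accumulated point count above the
# density threshold are retained, and each parent cube emits the
# count-weighted mean of its retained sub-cube centroids. Iterating with the
# edge length doubled each pass thins the cloud toward the medial structure.
# Across iterations every point carries the number of original points it
# represents, so the density threshold keeps its meaning as the cloud thins;
# at the first iteration the weights are all one and the computation is the
# plain per-sub-cube count and centroid.

# integer sub-cube coordinates, half-open [lo, hi) membership
.subcube_key <- function(p, lo, half) {
  ix <- floor((p[, 1] - lo[1]) / half)
  iy <- floor((p[, 2] - lo[2]) / half)
  iz <- floor((p[, 3] - lo[3]) / half)
  cbind(ix, iy, iz)
}

#' Partition a cloud into parent cubes and half-edge sub-cubes
#'
#' The grid is anchored at the cloud's minimum corner (making the pipeline
#' translation-equivariant) and every point is assigned by half-open interval
#' membership.
#'
#' @param cloud a \linkS4class{PlantCloud} or an n x 3 matrix
#' @param L parent cube edge length (m)
#' @param weights optional per-point accumulated counts (default 1)
#' @return list of class \code{"VoxelPartition"}: per-point \code{sub_id} and
#'   \code{parent_id} (integer codes), a \code{sub_table} data.frame with
#'   sub-cube ids, parent ids, accumulated counts \code{m} and centroids, and
#'   the grid anchor \code{lo}.
#' @export
partitionVoxels <- function(cloud, L, weights = NULL) {
  p <- if (is(cloud, "PlantCloud")) coords(cloud) else as.matrix(cloud)
  if (nrow(p) == 0) stop("cannot partition an empty cloud")
  if (L <= 0) stop("L must be > 0")
  if (is.null(weights)) weights <- rep(1, nrow(p))
  stopifnot(length(weights) == nrow(p))
  lo <- apply(p, 2, min)
  sc <- .subcube_key(p, lo, L / 2)
  # integer codes: sub-cube index and its parent cube (floor of half)
  pc <- floor(sc / 2)
  sub_id <- paste(sc[, 1], sc[, 2], sc[, 3])
  parent_id <- paste(pc[, 1], pc[, 2], pc[, 3])
  usub <- !duplicated(sub_id)
  sub_levels <- sub_id[usub]
  fs <- factor(sub_id, levels = sub_levels)
  m <- as.numeric(rowsum(weights, fs))
  cent <- rowsum(p * weights, fs) / m
  sub_table <- data.frame(sub = sub_levels, parent = parent_id[usub],
                          m = m, cx = cent[, 1], cy = cent[, 2],
                          cz = cent[, 3], stringsAsFactors = FALSE)
  structure(list(L = L, lo = lo, sub_id = sub_id, parent_id = parent_id,
                 sub_table = sub_table, n_points = nrow(p)),
            class = "VoxelPartition")
}

#' Geometric centroid of a sub-cube's points
#'
#' @param points m x 3 matrix of the sub-cube's member points
#' @return the arithmetic mean point
#' @export
subCubeCentroid <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("empty sub-cube has no centroid")
  colMeans(points)
}

#' Density-weighted centroids per parent cube
#'
#' Sub-cubes with accumulated count \code{m > theta} (strict) are retained;
#' each parent cube with at least one retained sub-cube emits
#' \eqn{C_w = \sum m_j C_j / \sum m_j} over its retained sub-cubes, which
#' equals the weighted mean of all points they contain.
#'
#' @param partition a \code{\link{partitionVoxels}} result
#' @param theta density threshold (count); retained iff \code{m > theta}
#' @return list with \code{points} (k x 3 weighted centroids) and
#'   \code{counts} (accumulated source-point counts per skeleton point);
#'   zero rows if every sub-cube is discarded.
#' @export
weightedCentroids <- function(partition, theta) {
  stopifnot(inherits(partition, "VoxelPartition"), theta >= 0)
  st <- partition$sub_table[partition$sub_table$m > theta, , drop = FALSE]
  if (nrow(st) == 0)
    return(list(points = matrix(numeric(0), 0, 3), counts = numeric(0)))
  fp <- factor(st$parent, levels = unique(st$parent))
  msum <- as.numeric(rowsum(st$m, fp))
  cw <- rowsum(cbind(st$cx, st$cy, st$cz) * st$m, fp) / msum
  colnames(cw) <- c("x", "y", "z")
  list(points = unname(cw), counts = msum)
}

#' Iterative density-weighted voxel-centroid skeletonization
#'
#' Repeats \{partition, weighted centroids\} with the parent edge length
#' doubled each pass (\code{L0 * 2^(k-1)} at pass k). Defaults: initial edge
#' 0.01 m, density threshold 6, three passes.
#'
#' @param cloud a \linkS4class{PlantCloud} or n x 3 matrix
#' @param L0 initial parent cube edge length (m)
#' @param theta density threshold (strict, on accumulated counts)
#' @param n_iter number of passes
#' @param method \code{"density"} (the default, sub-cube filtered weighted
#'   centroids) or \code{"geometric"}, a comparison baseline emitting the
#'   plain unfiltered centroid of every occupied parent cube
#' @return a \linkS4class{PlantCloud} of skeleton points; metadata carries
#'   \code{counts} (source points represented by each skeleton point),
#'   \code{iterations} actually run, and the per-pass point counts.
#' @export
#' @examples
#' pl <- generatePlant(plantSpec(n_leaves = 0, noise_sigma = 0,
#'                               outlier_count = 0, seed = 1))
#' sk <- skeletonize(pl$cloud)
#' nPoints(sk)
skeletonize <- function(cloud, L0 = 0.01, theta = 6, n_iter = 3,
                        method = c("density", "geometric")) {
  method <- match.arg(method)
  if (method == "geometric") theta <- 0   # retain every occupied sub-cube
  if (n_iter < 1) stop("n_iter must be >= 1")
  p <- if (is(cloud, "PlantCloud")) coords(cloud) else as.matrix(cloud)
  if (nrow(p) == 0) stop("cannot skeletonize an empty cloud")
  w <- rep(1, nrow(p))
  sizes <- integer(0)
  for (k in seq_len(n_iter)) {
    L <- L0 * 2^(k - 1)
    wc <- weightedCentroids(partitionVoxels(p, L, w), theta)
    if (nrow(wc$points) < 2) {
      warning("skeleton collapsed to fewer than 2 points at iteration ", k,
              "; returning the previous pass")
      k <- k - 1
      break
    }
    p <- wc$points
    w <- wc$counts
    sizes <- c(sizes, nrow(p))
  }
  if (length(sizes) == 0)
    stop("skeletonization produced no usable points; lower theta or L0")
  plantCloud(p, metadata = list(counts = w, iterations = length(sizes),
                                sizes_per_iteration = sizes,
                                L0 = L0, theta = theta))
}
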