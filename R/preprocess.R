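# Denoising of merged plant clouds before skeletonization. Registration of
# the multi-view scans is assumed done upstream; this module provides the
# statistical outlier removal (SOR) filter and an axis-aligned crop.

#' SOR filter configuration
#'
#' Defaults suit denoising of merged time-of-flight seedling scans:
#' K = 100 neighbours, standard-deviation multiplier 1.1.
#'
#' @param k_neighbors number of nearest neighbours per point (excluding the
#'   point itself).
#' @param std_multiplier threshold multiplier on the global standard deviation.
#' @return list of class \code{"SORConfig"}
#' @export
sorConfig <- function(k_neighbors = 100L, std_multiplier = 1.1) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (std_multiplier <= 0) stop("std_multiplier must be > 0")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 std_multiplier = std_multiplier), class = "SORConfig")
}

#' Statistical outlier removal
#'
#' For each point the mean distance to its k nearest neighbours (the point
#' itself excluded) is computed; points whose mean distance exceeds
#' \code{global mean + std_multiplier * global sd} are removed. Statistics are
#' computed once on the input cloud (single pass). The order of kept points is
#' preserved.
#'
#' @param cloud a \linkS4class{PlantCloud}
#' @param cfg a \code{\link{sorConfig}}
#' @return list with \code{cloud} (kept points) and \code{removed} (1-based
#'   indices into the input cloud)
#' @export
#' @examples
#' pl <- generatePlant(plantSpec(n_leaves = 2, points_per_m2 = 2e5, seed = 3))
#' f <- sorFilter(pl$cloud, sorConfig(20, 1.1))
#' length(f$removed)
sorFilter <- function(cloud, cfg = sorConfig()) {
  stopifnot(is(cloud, "PlantCloud"), inherits(cfg, "SORConfig"))
  n <- nPoints(cloud)
  k <- cfg$k_neighbors
  if (n <= k)
    stop("SOR needs more than k_neighbors = ", k, " points (got ", n, ")")
  p <- coords(cloud)
  nn <- cpp_knn(p, p, k + 1L)           # first neighbour is the point itself
  mean_d <- rowMeans(nn$dist[, -1, drop = FALSE])
  thr <- mean(mean_d) + cfg$std_multiplier * stats::sd(mean_d)
  # relative guard so exact-tie distances (lattices) never trip on ULP noise
  removed <- which(mean_d > thr + 1e-12 * abs(thr))
  keep <- setdiff(seq_len(n), removed)
  kept <- plantCloud(p[keep, , drop = FALSE],
                     labels = if (length(cloud@labels)) cloud@labels[keep]
                              else character(0),
                     metadata = cloud@metadata)
  list(cloud = kept, removed = removed)
}

#' Axis-aligned box crop
#'
#' Keeps points with every coordinate inside the closed box. Stands in for
#' background/pot removal of bench scans.
#'
#' @param cloud a \linkS4class{PlantCloud}
#' @param min_corner,max_corner numeric length-3 box corners (m),
#'   componentwise \code{min_corner < max_corner}.
#' @return the cropped \linkS4class{PlantCloud}; warns if empty.
#' @export
cropBox <- function(cloud, min_corner, max_corner) {
  stopifnot(is(cloud, "PlantCloud"),
            length(min_corner) == 3, length(max_corner) == 3)
  if (any(min_corner >= max_corner))
    stop("min_corner must be componentwise smaller than max_corner")
  p <- coords(cloud)
  keep <- p[, 1] >= min_corner[1] & p[, 1] <= max_corner[1] &
          p[, 2] >= min_corner[2] & p[, 2] <= max_corner[2] &
          p[, 3] >= min_corner[3] & p[, 3] <= max_corner[3]
  if (!any(keep)) warning("cropBox: no points inside the box")
  plantCloud(p[keep, , drop = FALSE],
             labels = if (length(cloud@labels)) cloud@labels[keep]
                      else character(0),
             metadata = cloud@metadata)
}
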