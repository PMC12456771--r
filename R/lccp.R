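# LCCP merging: supervoxels connected by locally convex adjacencies are
# unioned into coarse clusters; concave boundaries (leaf-leaf creases,
# stem-leaf junctions) stay cut.

#' LCCP configuration
#'
#' Defaults: concavity tolerance 20 degrees,
#' smoothness threshold 0.1, and retention of clusters with more than 100
#' points only.
#'
#' @param beta_th concavity tolerance in degrees, in (0, 90)
#' @param theta_th smoothness threshold (radians of normal-angle difference
#'   below which an adjacency is always considered convex)
#' @param min_cluster_points clusters with at most this many points are
#'   dropped (label 0)
#' @return list of class \code{"LCCPConfig"}
#' @export
lccpConfig <- function(beta_th = 20, theta_th = 0.1,
                       min_cluster_points = 100L) {
  if (beta_th <= 0 || beta_th >= 90) stop("beta_th must be in (0, 90) degrees")
  if (min_cluster_points < 0) stop("min_cluster_points must be >= 0")
  structure(list(beta_th = beta_th, theta_th = theta_th,
                 min_cluster_points = as.integer(min_cluster_points)),
            class = "LCCPConfig")
}

# extended convexity of one supervoxel adjacency:
#   d = x_i - x_j; convex iff (n_i - n_j) . d_hat >= -sin(beta_th),
# gated by the smoothness threshold (near-parallel normals are always
# convex) and a sanity criterion suppressing the singular configuration in
# which the connecting direction runs along the normals' intersection line.
.edge_convex <- function(n_i, n_j, x_i, x_j, cfg) {
  d <- x_i - x_j
  dn <- sqrt(sum(d^2))
  if (dn == 0) return(TRUE)
  d <- d / dn
  cosang <- min(1, max(-1, sum(n_i * n_j)))
  ang <- acos(cosang)
  if (ang <= cfg$theta_th) return(TRUE)
  s <- c(n_i[2] * n_j[3] - n_i[3] * n_j[2],
         n_i[3] * n_j[1] - n_i[1] * n_j[3],
         n_i[1] * n_j[2] - n_i[2] * n_j[1])
  sn <- sqrt(sum(s^2))
  if (sn > 1e-12) {
    # sanity criterion: d should be roughly perpendicular to the fold line s
    cos_sd <- abs(sum(s / sn * d))
    if (cos_sd > cos(60 * pi / 180)) return(FALSE)
  }
  sum((n_i - n_j) * d) >= -sin(cfg$beta_th * pi / 180)
}

#' Merge supervoxels across locally convex adjacencies
#'
#' Classifies every supervoxel adjacency as convex or concave
#' (extended-convexity criterion with \code{beta_th} tolerance, smoothness
#' gate and sanity criterion), takes connected components over convex edges,
#' and drops components holding \code{<= min_cluster_points} points.
#'
#' @param sv a \code{\link{vccsSupervoxels}} result
#' @param cfg a \code{\link{lccpConfig}}
#' @return list with \code{point_label} (per input point; 0 = dropped),
#'   \code{sv_cluster} (per supervoxel component id), and \code{sizes}
#'   (points per retained cluster, named by label)
#' @export
lccpMerge <- function(sv, cfg = lccpConfig()) {
  stopifnot(inherits(sv, "Supervoxels"), inherits(cfg, "LCCPConfig"))
  ns <- sv$n
  uf <- seq_len(ns)
  find <- function(i) {
    root <- i
    while (uf[root] != root) root <- uf[root]
    while (uf[i] != root) { nxt <- uf[i]; uf[i] <<- root; i <- nxt }
    root
  }
  for (i in seq_len(ns)) {
    for (j in sv$adjacency[[i]]) {
      if (j <= i) next  # symmetric: handle each pair once
      if (.edge_convex(sv$normal[i, ], sv$normal[j, ],
                       sv$centroid[i, ], sv$centroid[j, ], cfg)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) uf[min(ri, rj)] <- max(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(ns), find, integer(1))
  comp <- match(comp, unique(comp))
  pt <- comp[sv$point_label]
  sizes <- tabulate(pt, nbins = max(comp))
  keep <- which(sizes > cfg$min_cluster_points)
  relab <- integer(max(comp))
  relab[keep] <- seq_along(keep)
  point_label <- ifelse(pt %in% keep, relab[pt], 0L)
  list(point_label = as.integer(point_label),
       sv_cluster = comp,
       sizes = sizes[keep])
}
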