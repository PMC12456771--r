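# Adaptive K-means++ refinement of under-segmented (adherent) leaves.

#' K-means++ configuration
#'
#' Defaults: at most 100 Lloyd iterations,
#' convergence threshold 0.1 cm on center movement, minimum initial center
#' separation 0.2 cm.
#'
#' @param max_iter Lloyd iteration cap
#' @param tol convergence threshold on the largest center shift (m)
#' @param min_center_sep minimum distance between accepted initial centers (m)
#' @param seed RNG seed for the D^2 seeding draws
#' @return list of class \code{"KMeansConfig"}
#' @export
kmeansConfig <- function(max_iter = 100L, tol = 0.001,
                         min_center_sep = 0.002, seed = 1L) {
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 min_center_sep = min_center_sep, seed = as.integer(seed)),
            class = "KMeansConfig")
}

#' Adaptive cluster count for anomalous leaves
#'
#' Computes the mean cluster size \eqn{\bar\mu}, flags clusters with
#' \eqn{S_i > \bar\mu} as anomalous, and assigns each anomalous cluster
#' \eqn{K = \lfloor S_e / \bar\mu \rfloor}; a K below 2 means the cluster is
#' kept whole.
#'
#' @param cluster_sizes integer vector of coarse cluster point counts
#' @return data.frame with columns \code{cluster}, \code{size}, \code{k}
#'   (k = 1 for clusters that are not split), plus attribute
#'   \code{mean_size}
#' @export
#' @examples
#' adaptiveK(c(100, 100, 500))  # K = 2 for the 500-point cluster
adaptiveK <- function(cluster_sizes) {
  if (!length(cluster_sizes)) stop("need at least one cluster")
  mu <- mean(cluster_sizes)
  k <- rep(1L, length(cluster_sizes))
  anom <- cluster_sizes > mu
  k[anom] <- pmax(1L, as.integer(floor(cluster_sizes[anom] / mu)))
  k[k < 2] <- 1L
  structure(data.frame(cluster = seq_along(cluster_sizes),
                       size = as.integer(cluster_sizes), k = k),
            mean_size = mu)
}

#' K-means++ split of one cluster
#'
#' D^2 seeding with rejection of candidate centers closer than
#' \code{min_center_sep} to an accepted center (after 50 failed draws the
#' separation is halved with a warning), followed by Lloyd iterations on XYZ
#' until the largest center shift drops below \code{tol} or \code{max_iter}
#' is reached. Deterministic for a fixed config seed.
#'
#' @param points n x 3 matrix of the cluster's points
#' @param K number of sub-clusters, \code{2 <= K <= n}
#' @param cfg a \code{\link{kmeansConfig}}
#' @return integer vector of sub-cluster labels 1..K
#' @export
kmeansppSplit <- function(points, K, cfg = kmeansConfig()) {
  p <- as.matrix(points)
  n <- nrow(p)
  stopifnot(K >= 2, n >= K)
  .with_seed(cfg$seed, {
    sep <- cfg$min_center_sep
    centers <- matrix(NA_real_, K, 3)
    centers[1, ] <- p[sample.int(n, 1), ]
    d2 <- rowSums(sweep(p, 2, centers[1, ])^2)
    for (k in 2:K) {
      placed <- FALSE
      for (attempt in seq_len(50)) {
        prob <- d2 / sum(d2)
        cand <- p[sample.int(n, 1, prob = prob), ]
        cd <- sqrt(rowSums(sweep(centers[seq_len(k - 1), , drop = FALSE],
                                 2, cand)^2))
        if (all(cd >= sep)) { placed <- TRUE; break }
      }
      if (!placed) {
        warning("could not place separated centers; relaxing separation")
        sep <- sep / 2
        prob <- d2 / sum(d2)
        cand <- p[sample.int(n, 1, prob = prob), ]
      }
      centers[k, ] <- cand
      d2 <- pmin(d2, rowSums(sweep(p, 2, cand)^2))
    }
    lab <- integer(n)
    for (it in seq_len(cfg$max_iter)) {
      dmat <- vapply(seq_len(K), function(k)
        rowSums(sweep(p, 2, centers[k, ])^2), numeric(n))
      lab <- max.col(-dmat, ties.method = "first")
      shift <- 0
      for (k in seq_len(K)) {
        members <- lab == k
        if (!any(members)) next
        nc <- colMeans(p[members, , drop = FALSE])
        shift <- max(shift, sqrt(sum((nc - centers[k, ])^2)))
        centers[k, ] <- nc
      }
      if (shift < cfg$tol) break
    }
    lab
  })
}

#' Segment a leaf cloud into leaf instances
#'
#' Runs the full leaf pipeline: VCCS supervoxels, LCCP convexity merging,
#' the adaptive-K rule on coarse cluster sizes, and K-means++ splitting of
#' anomalous clusters. Final labels are compacted to 1..m; points dropped by
#' the minimum-cluster-size filter keep label 0.
#'
#' @param leaf_cloud a \linkS4class{PlantCloud} (the full cloud minus stem)
#' @param vccs_cfg a \code{\link{vccsConfig}}
#' @param lccp_cfg a \code{\link{lccpConfig}}
#' @param km_cfg a \code{\link{kmeansConfig}}
#' @return a \linkS4class{LeafSegmentation}
#' @export
segmentLeaves <- function(leaf_cloud, vccs_cfg = vccsConfig(),
                          lccp_cfg = lccpConfig(), km_cfg = kmeansConfig()) {
  stopifnot(nPoints(leaf_cloud) > 0)
  sv <- vccsSupervoxels(leaf_cloud, vccs_cfg)
  coarse <- lccpMerge(sv, lccp_cfg)
  lab <- coarse$point_label
  sizes <- as.integer(coarse$sizes)
  if (!length(sizes))
    return(new("LeafSegmentation", labels = lab, sizes = sizes,
               meanSize = NA_real_, kTable = data.frame()))
  ktab <- adaptiveK(sizes)
  mu <- attr(ktab, "mean_size")
  p <- coords(leaf_cloud)
  out <- lab
  next_id <- max(lab)
  for (r in which(ktab$k >= 2)) {
    idx <- which(lab == ktab$cluster[r])
    sub <- kmeansppSplit(p[idx, , drop = FALSE], ktab$k[r], km_cfg)
    # first sub-cluster keeps the original id, the rest get fresh ids
    for (s in 2:ktab$k[r]) {
      next_id <- next_id + 1L
      out[idx[sub == s]] <- next_id
    }
  }
  pos <- out > 0
  out[pos] <- match(out[pos], sort(unique(out[pos])))
  new("LeafSegmentation", labels = as.integer(out), sizes = sizes,
      meanSize = mu, kTable = ktab[ktab$k >= 2, , drop = FALSE])
}
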