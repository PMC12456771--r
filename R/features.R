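# Local surface features: PCA normals with curvature, and the 33-bin Fast
# Point Feature Histogram used by the supervoxel similarity metric.

#' Per-point normals and curvature from k-nearest-neighbour PCA
#'
#' The normal is the eigenvector of the neighbourhood covariance with the
#' smallest eigenvalue, sign-oriented away from the cloud centroid; curvature
#' is the surface-variation ratio \eqn{\lambda_0/(\lambda_0+\lambda_1+\lambda_2)}
#' in [0, 1/3].
#'
#' @param points n x 3 matrix or \linkS4class{PlantCloud}
#' @param k neighbourhood size (the point itself is included)
#' @return list with \code{normals} (n x 3 unit vectors) and
#'   \code{curvature} (length n)
#' @export
normalsCurvature <- function(points, k = 16L) {
  p <- if (is(points, "PlantCloud")) coords(points) else as.matrix(points)
  n <- nrow(p)
  if (n < k) stop("need at least k = ", k, " points")
  nn <- cpp_knn(p, p, as.integer(k))$index
  ctr <- colMeans(p)
  normals <- matrix(0, n, 3)
  curv <- numeric(n)
  degen <- FALSE
  for (i in seq_len(n)) {
    q <- p[nn[i, ], , drop = FALSE]
    q <- sweep(q, 2, colMeans(q))
    ev <- eigen(crossprod(q), symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    tot <- sum(lam)
    if (tot <= 0) { degen <- TRUE; normals[i, ] <- c(0, 1, 0); next }
    curv[i] <- lam[3] / tot
    nv <- ev$vectors[, 3]
    out <- p[i, ] - ctr
    if (sum(nv * out) < 0) nv <- -nv
    normals[i, ] <- nv
  }
  if (degen) warning("degenerate neighbourhoods encountered; ",
                     "their curvature was set to 0")
  list(normals = normals, curvature = curv)
}

# Darboux-frame pair angles (alpha, phi, theta) between a source point/normal
# and a set of target points/normals. Source choice follows the usual
# convention: the endpoint whose normal makes the smaller angle with the
# connecting line acts as source.
.pair_angles <- function(pi_, ni_, pj, nj) {
  d <- pj - matrix(pi_, nrow(pj), 3, byrow = TRUE)
  len <- sqrt(rowSums(d^2))
  ok <- len > 0
  d <- d[ok, , drop = FALSE] / len[ok]
  pj <- pj[ok, , drop = FALSE]; nj <- nj[ok, , drop = FALSE]
  m <- nrow(d)
  if (!m) return(NULL)
  ni <- matrix(ni_, m, 3, byrow = TRUE)
  cos_i <- abs(rowSums(ni * d))
  cos_j <- abs(rowSums(nj * -d))
  swap <- cos_j > cos_i
  ns <- ni; nt <- nj
  if (any(swap)) {
    ns[swap, ] <- nj[swap, , drop = FALSE]
    nt[swap, ] <- ni[swap, , drop = FALSE]
    d[swap, ] <- -d[swap, , drop = FALSE]
  }
  u <- ns
  v <- .cross(d, u)
  vn <- sqrt(rowSums(v^2))
  vn[vn == 0] <- 1
  v <- v / vn
  w <- .cross(u, v)
  alpha <- rowSums(v * nt)                    # in [-1, 1]
  phi <- rowSums(u * d)                       # in [-1, 1]
  theta <- atan2(rowSums(w * nt), rowSums(u * nt))  # in [-pi, pi]
  cbind(alpha, phi, theta)
}

.spfh_hist <- function(ang) {
  if (is.null(ang) || nrow(ang) == 0) return(numeric(33))
  b1 <- pmin(pmax(floor((ang[, 1] + 1) / 2 * 11) + 1, 1), 11)
  b2 <- pmin(pmax(floor((ang[, 2] + 1) / 2 * 11) + 1, 1), 11)
  b3 <- pmin(pmax(floor((ang[, 3] + pi) / (2 * pi) * 11) + 1, 1), 11)
  c(tabulate(b1, 11), tabulate(b2, 11), tabulate(b3, 11))
}

#' Fast Point Feature Histograms
#'
#' Standard 33-dimensional FPFH: three Darboux pair-angle features over the
#' radius neighbourhood, 11 bins each; each point's simplified histogram
#' (SPFH) is combined with its neighbours' SPFHs weighted by inverse
#' distance, and each 11-bin block is normalized to sum 100.
#'
#' @param points n x 3 matrix or \linkS4class{PlantCloud}
#' @param normals n x 3 unit normals (see \code{\link{normalsCurvature}})
#' @param radius neighbourhood radius in meters
#' @return n x 33 matrix; isolated points yield a zero histogram (warning)
#' @export
fpfh <- function(points, normals, radius) {
  p <- if (is(points, "PlantCloud")) coords(points) else as.matrix(points)
  n <- nrow(p)
  stopifnot(nrow(normals) == n, radius > 0)
  nbr <- cpp_radius(p, p, radius)
  spfh <- matrix(0, n, 33)
  for (i in seq_len(n)) {
    js <- setdiff(nbr[[i]], i)
    if (!length(js)) next
    spfh[i, ] <- .spfh_hist(.pair_angles(p[i, ], normals[i, ],
                                         p[js, , drop = FALSE],
                                         normals[js, , drop = FALSE]))
  }
  out <- matrix(0, n, 33)
  isolated <- FALSE
  for (i in seq_len(n)) {
    js <- setdiff(nbr[[i]], i)
    if (!length(js)) { isolated <- TRUE; next }
    wdist <- sqrt(rowSums((p[js, , drop = FALSE] -
                           matrix(p[i, ], length(js), 3, byrow = TRUE))^2))
    wdist[wdist == 0] <- min(wdist[wdist > 0], radius / 100)
    h <- spfh[i, ] + colSums(spfh[js, , drop = FALSE] / wdist) / length(js)
    out[i, ] <- h
  }
  if (isolated) warning("isolated points received a zero FPFH histogram")
  # block-normalize to sum 100 per 11-bin feature
  for (b in 0:2) {
    cols <- b * 11 + 1:11
    s <- rowSums(out[, cols, drop = FALSE])
    s[s == 0] <- 1
    out[, cols] <- out[, cols, drop = FALSE] / s * 100
  }
  out
}
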