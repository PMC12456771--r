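# Phenotypic trait extraction: plant height (Y extent), stem length (arc
# length of the smoothed stem curve), stem diameter (ellipse fits to thin
# cross-sectional slices along the stem's principal axis) and leaf area
# (triangulated leaf meshes with boundary-ring hole repair).

#' Plant height
#'
#' \eqn{H = Y_{max} - Y_{min}} over the preprocessed cloud (gravity along +Y).
#'
#' @param cloud a \linkS4class{PlantCloud} or n x 3 matrix
#' @return height in meters
#' @export
plantHeight <- function(cloud) {
  p <- if (is(cloud, "PlantCloud")) coords(cloud) else as.matrix(cloud)
  if (nrow(p) == 0) stop("empty cloud has no height")
  max(p[, 2]) - min(p[, 2])
}

#' Stem length: arc length of the stem curve
#'
#' Sum of Euclidean distances between consecutive curve samples.
#'
#' @param curve a \linkS4class{StemCurve} or an ordered m x 3 matrix
#' @return length in meters
#' @export
stemLength <- function(curve) {
  s <- if (is(curve, "StemCurve")) curve@samples else as.matrix(curve)
  if (nrow(s) < 2) stop("need at least 2 curve samples")
  sum(sqrt(rowSums(diff(s)^2)))
}

#' Direct least-squares ellipse fit
#'
#' Numerically stable direct conic fit constrained to an ellipse
#' (Halir-Flusser formulation of the Fitzgibbon fit), with center, semi-axes
#' (a >= b), rotation and an RMS geometric residual derived from the conic.
#'
#' @param points_2d n x 2 matrix, n >= 6, not collinear
#' @return list of class \code{"EllipseFit"}: \code{center}, \code{semi_axes}
#'   (a >= b), \code{rotation} (radians), \code{rms_residual},
#'   \code{conic} coefficients (A, B, C, D, E, F)
#' @export
fitEllipse <- function(points_2d) {
  q <- as.matrix(points_2d)
  if (ncol(q) != 2) stop("points_2d must have 2 columns")
  if (nrow(q) < 6) stop("ellipse fitting needs at least 6 points")
  ctr0 <- colMeans(q)
  z <- sweep(q, 2, ctr0)
  scl <- sqrt(mean(rowSums(z^2)))
  if (scl <= 0) stop("degenerate input: all points coincide")
  z <- z / scl
  x <- z[, 1]; y <- z[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate (collinear?) input for ellipse fitting"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("no ellipse solution for the given points")
  a1 <- evec[, ok[1]]
  conic_s <- c(a1, drop(Tm %*% a1))  # A B C D E F in scaled frame
  # unscale: substitute x -> (x - cx)/s, y -> (y - cy)/s
  A <- conic_s[1]; B <- conic_s[2]; C <- conic_s[3]
  D <- conic_s[4]; E <- conic_s[5]; Fc <- conic_s[6]
  s <- scl; cx <- ctr0[1]; cy <- ctr0[2]
  A2 <- A / s^2; B2 <- B / s^2; C2 <- C / s^2
  D2c <- D / s - 2 * A * cx / s^2 - B * cy / s^2
  E2 <- E / s - 2 * C * cy / s^2 - B * cx / s^2
  F2 <- A * cx^2 / s^2 + B * cx * cy / s^2 + C * cy^2 / s^2 -
    D * cx / s - E * cy / s + Fc
  conic <- c(A = A2, B = B2, C = C2, D = D2c, E = E2, F = F2)
  disc <- B2^2 - 4 * A2 * C2
  if (disc >= 0) stop("fitted conic is not an ellipse")
  x0 <- (2 * C2 * D2c - B2 * E2) / disc
  y0 <- (2 * A2 * E2 - B2 * D2c) / disc
  num <- 2 * (A2 * E2^2 + C2 * D2c^2 - B2 * D2c * E2 + disc * F2)
  root <- sqrt((A2 - C2)^2 + B2^2)
  ax1 <- -sqrt(num * (A2 + C2 + root)) / disc
  ax2 <- -sqrt(num * (A2 + C2 - root)) / disc
  semi <- sort(c(ax1, ax2), decreasing = TRUE)
  if (any(!is.finite(semi)) || any(semi <= 0))
    stop("degenerate ellipse fit")
  rot <- 0.5 * atan2(-B2, C2 - A2)
  # geometric residual via first-order (Sampson) approximation
  xx <- q[, 1]; yy <- q[, 2]
  Q <- A2 * xx^2 + B2 * xx * yy + C2 * yy^2 + D2c * xx + E2 * yy + F2
  gx <- 2 * A2 * xx + B2 * yy + D2c
  gy <- 2 * C2 * yy + B2 * xx + E2
  gn <- sqrt(gx^2 + gy^2)
  gn[gn == 0] <- Inf
  rms <- sqrt(mean((Q / gn)^2))
  structure(list(center = unname(c(x0, y0)), semi_axes = unname(semi),
                 rotation = unname(rot),
                 rms_residual = rms, conic = conic), class = "EllipseFit")
}

#' Stem diameter by ellipse-fitted cross-sectional slices
#'
#' PCA gives the stem's principal axis; thin slices perpendicular to that
#' axis are taken at fixed stations above the stem base (defaults: four
#' slices at 5, 6, 7, 8 cm, 2 mm thick), each slice is projected onto the
#' plane orthogonal to the axis and fitted with an ellipse, and the minor
#' semi-axes are averaged. By default the diameter is twice the mean minor
#' semi-axis (a circular stem of radius r has minor semi-axis r);
#' \code{literal_minor_axis = TRUE} reports the unscaled mean instead.
#'
#' @param stem_cloud a \linkS4class{PlantCloud} or n x 3 matrix of stem points
#' @param slice_start first station above the stem base (m)
#' @param slice_spacing station spacing (m)
#' @param n_slices number of slices
#' @param slice_thickness slice thickness (m)
#' @param literal_minor_axis report \code{mean(b)} instead of \code{2 mean(b)}
#' @return diameter in meters; slices with fewer than 6 points are skipped
#'   with a warning, and an error is raised if every slice is skipped
#' @export
stemDiameter <- function(stem_cloud, slice_start = 0.05,
                         slice_spacing = 0.01, n_slices = 4L,
                         slice_thickness = 0.002,
                         literal_minor_axis = FALSE) {
  p <- if (is(stem_cloud, "PlantCloud")) coords(stem_cloud) else
    as.matrix(stem_cloud)
  if (nrow(p) < 6) stop("too few stem points")
  line <- principalDirection(p)
  t <- drop(sweep(p, 2, line$anchor) %*% line$direction)
  base <- min(t)
  span <- max(t) - base
  need <- slice_start + (n_slices - 1) * slice_spacing
  if (span < need)
    stop(sprintf("stem spans %.3f m along its axis but slicing needs %.3f m",
                 span, need))
  # orthonormal in-plane basis
  ref <- if (abs(line$direction[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- ref - sum(ref * line$direction) * line$direction
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross(matrix(line$direction, 1), matrix(e1, 1))[1, ]
  minors <- numeric(0)
  for (i in seq_len(n_slices)) {
    station <- base + slice_start + (i - 1) * slice_spacing
    inslice <- abs(t - station) <= slice_thickness / 2
    if (sum(inslice) < 6) {
      warning(sprintf("slice %d at %.3f m has %d points; skipped",
                      i, station - base, sum(inslice)))
      next
    }
    q <- sweep(p[inslice, , drop = FALSE], 2, line$anchor)
    uv <- cbind(drop(q %*% e1), drop(q %*% e2))
    fit <- tryCatch(fitEllipse(uv), error = function(e) NULL)
    if (is.null(fit)) {
      warning(sprintf("ellipse fit failed for slice %d; skipped", i))
      next
    }
    minors <- c(minors, fit$semi_axes[2])
  }
  if (!length(minors)) stop("every stem slice was skipped; no diameter")
  if (literal_minor_axis) mean(minors) else 2 * mean(minors)
}

#' Voxel-grid downsample (centroid per occupied voxel)
#'
#' @param cloud a \linkS4class{PlantCloud} or n x 3 matrix
#' @param voxel voxel edge length (m)
#' @return the downsampled point matrix
#' @export
downsampleCloud <- function(cloud, voxel) {
  p <- if (is(cloud, "PlantCloud")) coords(cloud) else as.matrix(cloud)
  stopifnot(voxel > 0, nrow(p) > 0)
  v <- .voxelize(p, voxel)
  v$centroid
}
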