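# Synthetic seedling generator. Emits merged, labeled point clouds that mimic
# a single-stemmed broadleaf seedling as seen by a registered multi-view depth
# scan: a thin, slightly bowed vertical stem densely sampled as a cylinder
# surface, elliptical planar leaves attached around the stem through short
# petiole stubs, Gaussian surface noise and sparse far outliers. Every cloud
# comes with analytic ground truth (per-point labels, height, stem arc length,
# diameter, per-leaf areas, axis samples).

#' Specify a synthetic seedling
#'
#' Defaults describe a mid-sized nursery seedling: 40 cm stem of 4 mm
#' diameter with a 2\% lateral bow, 8 leaves in golden-angle phyllotaxis with
#' the apical leaf just below the stem tip, 1 mm surface noise, 200 far
#' outliers and 2e6 points/m^2 sampling density (a few 10^4 points per plant).
#'
#' @param stem_height stem axis height in meters.
#' @param stem_radius stem cylinder radius in meters.
#' @param stem_curvature lateral bow amplitude as a fraction of stem height.
#' @param n_leaves number of leaves.
#' @param leaf_semi_axes n_leaves x 2 matrix (or length-2 vector, recycled) of
#'   ellipse semi-axes (a, b) in meters, a >= b.
#' @param leaf_attach_heights attachment heights as fractions of stem height,
#'   strictly inside (0, 1).
#' @param leaf_azimuths attachment azimuths in radians.
#' @param leaf_elevation leaf tilt above the horizontal plane, radians;
#'   scalar (recycled) or one value per leaf. The default gives mature
#'   leaves a 20 degree spread and the erect young leaves near the apex
#'   (attachment above 0.9) 45 degrees.
#' @param petiole_length petiole stub length in meters.
#' @param stem_density_factor stem sampling density multiplier relative to
#'   leaves. Registered multi-view scans oversample the always-visible stem:
#'   real seedling clouds carry 35--45\% of their points on the stem, far
#'   above its share of surface area; 2.5 reproduces that fraction.
#' @param noise_sigma Gaussian surface noise standard deviation (m).
#' @param outlier_count number of far outliers scattered in a 3x bounding box.
#' @param points_per_m2 surface sampling density (points per square meter).
#' @param seed RNG seed making the cloud reproducible.
#' @return a validated list of class \code{"PlantSpec"}
#' @export
#' @examples
#' sp <- plantSpec(n_leaves = 4, seed = 7)
#' pl <- generatePlant(sp)
#' pl$truth$true_leaf_areas
plantSpec <- function(stem_height = 0.40, stem_radius = 0.002,
                      stem_curvature = 0.01, n_leaves = 8,
                      leaf_semi_axes = c(0.035, 0.0175),
                      leaf_attach_heights = NULL, leaf_azimuths = NULL,
                      leaf_elevation = NULL,
                      stem_density_factor = 2.5,
                      petiole_length = 0.003, noise_sigma = 0.001,
                      outlier_count = 200, points_per_m2 = 1e6, seed = 1L) {
  fail <- function(field, msg) stop("invalid PlantSpec: field '", field, "' ",
                                    msg, call. = FALSE)
  if (!is.numeric(stem_height) || stem_height <= 0) fail("stem_height", "must be > 0")
  if (!is.numeric(stem_radius) || stem_radius <= 0) fail("stem_radius", "must be > 0")
  if (stem_curvature < 0) fail("stem_curvature", "must be >= 0")
  if (n_leaves < 0 || n_leaves != round(n_leaves)) fail("n_leaves", "must be a count")
  if (points_per_m2 <= 0) fail("points_per_m2", "must be > 0")
  if (stem_density_factor <= 0) fail("stem_density_factor", "must be > 0")
  if (noise_sigma < 0) fail("noise_sigma", "must be >= 0")
  if (outlier_count < 0) fail("outlier_count", "must be >= 0")
  if (n_leaves > 0) {
    ax <- leaf_semi_axes
    if (is.null(dim(ax))) ax <- matrix(ax, n_leaves, 2, byrow = TRUE)
    if (nrow(ax) != n_leaves || ncol(ax) != 2)
      fail("leaf_semi_axes", "must be an n_leaves x 2 matrix")
    if (any(ax[, 2] <= 0) || any(ax[, 1] < ax[, 2]))
      fail("leaf_semi_axes", "requires a >= b > 0")
    if (is.null(leaf_attach_heights)) {
      # apical pair just below the stem tip (the shoot terminates in young
      # leaves around the apical bud); the rest spread along the stem
      leaf_attach_heights <- switch(min(n_leaves, 3),
        0.98, c(0.94, 0.98),
        c(seq(0.25, 0.85, length.out = n_leaves - 2), 0.94, 0.98))
    }
    if (length(leaf_attach_heights) != n_leaves ||
        any(leaf_attach_heights <= 0) || any(leaf_attach_heights >= 1))
      fail("leaf_attach_heights", "must be n_leaves fractions strictly in (0, 1)")
    if (is.null(leaf_azimuths))  # golden-angle phyllotaxis
      leaf_azimuths <- (seq_len(n_leaves) - 1) * 2.39996322972865332
    if (length(leaf_azimuths) != n_leaves)
      fail("leaf_azimuths", "must have n_leaves entries")
    if (is.null(leaf_elevation))
      leaf_elevation <- ifelse(leaf_attach_heights >= 0.9,
                               45 * pi / 180, 20 * pi / 180)
    leaf_elevation <- rep_len(leaf_elevation, n_leaves)
    leaf_semi_axes <- ax
  } else {
    leaf_semi_axes <- matrix(numeric(0), 0, 2)
    leaf_attach_heights <- numeric(0)
    leaf_azimuths <- numeric(0)
    leaf_elevation <- numeric(0)
  }
  structure(list(stem_height = stem_height, stem_radius = stem_radius,
                 stem_curvature = stem_curvature, n_leaves = as.integer(n_leaves),
                 leaf_semi_axes = leaf_semi_axes,
                 leaf_attach_heights = leaf_attach_heights,
                 leaf_azimuths = leaf_azimuths, leaf_elevation = leaf_elevation,
                 stem_density_factor = stem_density_factor,
                 petiole_length = petiole_length, noise_sigma = noise_sigma,
                 outlier_count = as.integer(outlier_count),
                 points_per_m2 = points_per_m2, seed = as.integer(seed)),
            class = "PlantSpec")
}

#' Draw a random seedling specification
#'
#' Samples the study conditions used throughout the package's validation:
#' stem height uniform in 30--50 cm with a slight bow (stems of these
#' seedlings are typically erect), 5--10 leaves whose size shrinks toward
#' the apex (upper leaves are younger), an apical pair at the shoot tip,
#' 1 mm noise, 200 outliers.
#'
#' @param seed RNG seed; drives both the specification draw and the cloud.
#' @return a \code{"PlantSpec"}
#' @export
randomPlantSpec <- function(seed = 1L) {
  rs <- .with_seed(seed, {
    h <- runif(1, 0.30, 0.50)
    nl <- sample(5:10, 1)
    # regular internode spacing with jitter (alternate phyllotaxis: one
    # leaf per node), plus the apical pair at the shoot tip
    base <- seq(0.22, 0.85, length.out = nl - 2)
    gap <- if (nl > 3) diff(base[1:2]) else 0.2
    att <- c(pmin(0.88, pmax(0.20, base + runif(nl - 2, -0.2, 0.2) * gap)),
             0.94, 0.98)
    a_base <- runif(1, 0.038, 0.050)
    a <- a_base * (1 - 0.35 * att)
    a[att >= 0.9] <- 0.65 * a_base  # apical pair: youngest, smallest leaves
    list(h = h, nl = nl, a = a, att = att,
         curv = runif(1, 0.005, 0.015), r = runif(1, 0.0015, 0.0030))
  })
  plantSpec(stem_height = rs$h, stem_radius = rs$r, stem_curvature = rs$curv,
            n_leaves = rs$nl, leaf_semi_axes = cbind(rs$a, rs$a / 2),
            leaf_attach_heights = rs$att, seed = seed)
}

# run expr under a local RNG state derived from seed, restoring the caller's
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# stem axis: lateral sine bow in a seed-fixed direction, vertical along +Y.
# Returns a function t in [0,1] -> xyz and its derivative.
.stem_axis <- function(spec, bow_dir = 0) {
  A <- spec$stem_curvature * spec$stem_height
  H <- spec$stem_height
  ca <- cos(bow_dir); sa <- sin(bow_dir)
  pos <- function(t) cbind(A * sin(pi * t) * ca, H * t, A * sin(pi * t) * sa)
  der <- function(t) cbind(A * pi * cos(pi * t) * ca, rep(H, length(t)),
                           A * pi * cos(pi * t) * sa)
  list(pos = pos, der = der, A = A, H = H)
}

.arc_length <- function(axis, t0 = 0, t1 = 1, n = 4000) {
  t <- seq(t0, t1, length.out = n + 1)
  p <- axis$pos(t)
  sum(sqrt(rowSums(diff(p)^2)))
}

# orthonormal frame perpendicular to each tangent row
.perp_frame <- function(tang) {
  tang <- tang / sqrt(rowSums(tang^2))
  ref <- matrix(rep(c(1, 0, 0), each = nrow(tang)), ncol = 3)
  alt <- abs(tang[, 1]) > 0.9
  ref[alt, ] <- matrix(rep(c(0, 0, 1), each = sum(alt)), ncol = 3)
  n1 <- .cross(tang, ref)
  n1 <- n1 / sqrt(rowSums(n1^2))
  n2 <- .cross(tang, n1)
  list(n1 = n1, n2 = n2)
}

.cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Generate a labeled synthetic seedling cloud with analytic ground truth
#'
#' Stem points are sampled uniformly on the bowed cylinder surface, leaves on
#' planar elliptical patches attached through 3 mm petiole stubs, Gaussian
#' noise is applied along surface normals, and far outliers are scattered
#' uniformly in a 3x bounding box. Deterministic for a fixed spec seed.
#'
#' @param spec a \code{"PlantSpec"} from \code{\link{plantSpec}}.
#' @return list with elements \code{cloud} (a labeled
#'   \linkS4class{PlantCloud}) and \code{truth} (list: per_point_label,
#'   true_height, true_stem_length, true_stem_diameter, true_leaf_areas,
#'   stem_axis_samples, leaf_centers).
#' @export
generatePlant <- function(spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  .with_seed(spec$seed, .generate_plant_impl(spec))
}

.generate_plant_impl <- function(spec) {
  bow_dir <- runif(1, 0, 2 * pi)
  axis <- .stem_axis(spec, bow_dir)
  H <- spec$stem_height; r <- spec$stem_radius
  stem_len <- .arc_length(axis)

  ## stem surface, uniform by area: arc-length-uniform t, uniform angle
  n_stem <- max(10L, round(spec$stem_density_factor * spec$points_per_m2 *
                             2 * pi * r * stem_len))
  tgrid <- seq(0, 1, length.out = 2001)
  cum <- c(0, cumsum(sqrt(rowSums(diff(axis$pos(tgrid))^2))))
  t_of_s <- splinefun(cum, tgrid, method = "monoH.FC")
  ts <- t_of_s(runif(n_stem, 0, max(cum)))
  phis <- runif(n_stem, 0, 2 * pi)
  frame <- .perp_frame(axis$der(ts))
  stem_nrm <- frame$n1 * cos(phis) + frame$n2 * sin(phis)
  stem_pts <- axis$pos(ts) + r * stem_nrm
  pts <- stem_pts; nrm <- stem_nrm
  lab <- rep("stem", n_stem)

  ## leaves: planar elliptical patches + petiole stubs
  leaf_areas <- numeric(spec$n_leaves)
  leaf_centers <- matrix(NA_real_, spec$n_leaves, 3)
  if (spec$n_leaves > 0) {
    for (k in seq_len(spec$n_leaves)) {
      a <- spec$leaf_semi_axes[k, 1]; b <- spec$leaf_semi_axes[k, 2]
      leaf_areas[k] <- pi * a * b
      t_at <- spec$leaf_attach_heights[k]
      att <- drop(axis$pos(t_at))
      psi <- spec$leaf_azimuths[k]; el <- spec$leaf_elevation[k]
      # outward major-axis direction, tilted `el` above horizontal
      u <- c(cos(psi) * cos(el), sin(el), sin(psi) * cos(el))
      v <- c(-sin(psi), 0, cos(psi))                  # horizontal minor axis
      nvec <- .cross(matrix(u, 1), matrix(v, 1))[1, ] # leaf normal
      nvec <- nvec / sqrt(sum(nvec^2))
      # petiole stub: a thin cylinder from the stem surface along u
      pl <- spec$petiole_length
      n_pet <- max(5L, round(spec$stem_density_factor * spec$points_per_m2 *
                               2 * pi * (r / 2) * pl))
      tp <- runif(n_pet, 0, pl)
      php <- runif(n_pet, 0, 2 * pi)
      pet_n1 <- v; pet_n2 <- nvec
      pet_nrm <- outer(cos(php), pet_n1) + outer(sin(php), pet_n2)
      pet <- matrix(att, n_pet, 3, byrow = TRUE) + outer(tp + r, u) +
        (r / 2) * pet_nrm
      # elliptical blade centered one semi-major axis beyond the petiole
      ctr <- att + (r + pl + a) * u
      leaf_centers[k, ] <- ctr
      n_leafpts <- max(20L, round(spec$points_per_m2 * pi * a * b))
      rr <- sqrt(runif(n_leafpts)); th <- runif(n_leafpts, 0, 2 * pi)
      blade <- matrix(ctr, n_leafpts, 3, byrow = TRUE) +
        outer(a * rr * cos(th), u) + outer(b * rr * sin(th), v)
      pts <- rbind(pts, pet, blade)
      nrm <- rbind(nrm, pet_nrm,
                   matrix(nvec, n_leafpts, 3, byrow = TRUE))
      lab <- c(lab, rep(paste0("leaf_", k), n_pet + n_leafpts))
    }
  }

  ## analytic truth from the noiseless cloud
  true_height <- max(pts[, 2]) - min(pts[, 2])
  axis_samples <- axis$pos(seq(0, 1, length.out = max(2001, ceiling(H / 1e-4))))
  truth <- list(per_point_label = lab,
                true_height = true_height,
                true_stem_length = stem_len,
                true_stem_diameter = 2 * r,
                true_leaf_areas = leaf_areas,
                stem_axis_samples = axis_samples,
                leaf_centers = leaf_centers)

  ## surface noise along normals, then far outliers in a 3x bounding box
  if (spec$noise_sigma > 0)
    pts <- pts + nrm * rnorm(nrow(pts), 0, spec$noise_sigma)
  if (spec$outlier_count > 0) {
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    ctr <- (lo + hi) / 2; half <- (hi - lo) / 2
    out <- sapply(1:3, function(j)
      runif(spec$outlier_count, ctr[j] - 3 * half[j], ctr[j] + 3 * half[j]))
    out <- matrix(out, ncol = 3)
    pts <- rbind(pts, out)
    lab <- c(lab, rep("outlier", spec$outlier_count))
  }
  truth$per_point_label <- lab
  list(cloud = plantCloud(pts, labels = lab,
                          metadata = list(spec = spec)),
       truth = truth)
}

#' Write a synthetic fixture (PLY cloud + JSON ground truth)
#'
#' @param cloud a \linkS4class{PlantCloud}
#' @param truth the ground-truth list from \code{\link{generatePlant}}
#' @param dir output directory (created if missing)
#' @return invisibly, the two file paths written
#' @export
writeFixture <- function(cloud, truth, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir)
  ply <- file.path(dir, "cloud.ply")
  js <- file.path(dir, "truth.json")
  writePLY(cloud, ply)
  tr <- truth
  tr$stem_axis_samples <- unname(apply(truth$stem_axis_samples, 1, c,
                                       simplify = FALSE))
  jsonlite::write_json(tr, js, auto_unbox = TRUE, digits = NA)
  invisible(c(cloud = ply, truth = js))
}

#' Read a fixture written by \code{\link{writeFixture}}
#' @param dir fixture directory
#' @return list(cloud, truth)
#' @export
readFixture <- function(dir) {
  cloud <- readPLY(file.path(dir, "cloud.ply"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  tr$stem_axis_samples <- matrix(unlist(tr$stem_axis_samples), ncol = 3,
                                 byrow = TRUE)
  list(cloud = cloud, truth = tr)
}
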