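# End-to-end orchestration: preprocess -> skeletonize -> stem extraction ->
# leaf segmentation -> trait report, with per-stage logging and optional
# artifact export.

#' Pipeline configuration
#'
#' All stage parameters in one serializable list. Defaults: SOR k=100/1.1,
#' skeleton L0=0.01 m / theta=6 / 2 passes, 2 cm junction gate, VCCS
#' 8 mm/10 mm with weights 0.2/0.4/1, LCCP 20 degrees/0.1/100 points,
#' K-means++ 100 iterations/1 mm tolerance/2 mm center separation, diameter
#' slices at 5-8 cm. The methods vignette discusses each choice.
#'
#' @param sor a \code{\link{sorConfig}}
#' @param L0,theta,n_iter skeletonization parameters
#' @param junction_radius line-distance gate for junction/root search (m)
#' @param stem_radius known (measured) stem radius in meters, or NULL; when
#'   given, the stem label search radius is \code{stem_label_factor *
#'   stem_radius + stem_label_slack}, otherwise \code{stem_label_default}
#' @param stem_label_factor multiplier on the measured stem radius (2 =
#'   the measured diameter)
#' @param stem_label_slack additive tolerance (m) covering surface noise and
#'   the skeleton curve's lateral error; calibrated on synthetic validation
#'   plants
#' @param stem_label_default fallback stem label radius (m)
#' @param curve_step stem curve resampling step (m)
#' @param path_max_turn maximal turn angle (degrees) tolerated along the
#'   skeleton path before spline smoothing; sharper kinks (detours through a
#'   leaf-base node at a junction) are removed. NULL disables despiking.
#' @param anchor_base extend the stem path to the cloud base along its end
#'   tangent before smoothing (the skeleton contracts away from the stem
#'   foot by about half a final-pass cell; the root is at the soil surface)
#' @param vccs a \code{\link{vccsConfig}}
#' @param lccp a \code{\link{lccpConfig}}
#' @param kmeans a \code{\link{kmeansConfig}}
#' @param slice_start,slice_spacing,n_slices,slice_thickness stem diameter
#'   slicing parameters (m / counts)
#' @param mesh_voxel leaf downsampling voxel for meshing (m); averages
#'   surface noise before triangulation
#' @param mesh_mu,mesh_max_edge triangulation edge caps
#' @param double_sided halve mesh areas (two-face registered clouds)
#' @param seed seed threaded to the K-means++ stage
#' @return list of class \code{"PipelineConfig"}
#' @export
pipelineConfig <- function(sor = sorConfig(), L0 = 0.01, theta = 6,
                           n_iter = 2, junction_radius = 0.02,
                           stem_radius = NULL, stem_label_factor = 2,
                           stem_label_slack = 0.003,
                           stem_label_default = 0.007, curve_step = 0.001,
                           path_max_turn = 60, anchor_base = TRUE, vccs = vccsConfig(),
                           lccp = lccpConfig(), kmeans = kmeansConfig(),
                           slice_start = 0.05, slice_spacing = 0.01,
                           n_slices = 4L, slice_thickness = 0.002,
                           mesh_voxel = 0.0025, mesh_mu = 2.5,
                           mesh_max_edge = 0.02, double_sided = FALSE,
                           seed = 1L) {
  structure(list(sor = sor, L0 = L0, theta = theta, n_iter = n_iter,
                 junction_radius = junction_radius, stem_radius = stem_radius,
                 stem_label_factor = stem_label_factor,
                 stem_label_slack = stem_label_slack,
                 stem_label_default = stem_label_default,
                 curve_step = curve_step, path_max_turn = path_max_turn,
                 anchor_base = anchor_base,
                 vccs = vccs, lccp = lccp, kmeans = kmeans,
                 slice_start = slice_start, slice_spacing = slice_spacing,
                 n_slices = as.integer(n_slices),
                 slice_thickness = slice_thickness, mesh_voxel = mesh_voxel,
                 mesh_mu = mesh_mu, mesh_max_edge = mesh_max_edge,
                 double_sided = double_sided, seed = as.integer(seed)),
            class = "PipelineConfig")
}

# Remove abrupt-angle detours from the stem path: the MST often routes the
# trunk chain through a leaf-base node at junction heights (two short hops
# beat one long one), which kinks the path and inflates its arc length.
# Interior nodes are removed greedily, sharpest turn first, until every
# remaining turn is below the threshold.
.despike_path <- function(path_pts, max_turn_deg = 60) {
  turn <- function(p) {
    n <- nrow(p)
    if (n < 3) return(numeric(0))
    a <- p[2:(n - 1), , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
    b <- p[3:n, , drop = FALSE] - p[2:(n - 1), , drop = FALSE]
    na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
    cosv <- rowSums(a * b) / pmax(na * nb, 1e-300)
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  repeat {
    tv <- turn(path_pts)
    if (!length(tv) || max(tv) <= max_turn_deg) break
    path_pts <- path_pts[-(which.max(tv) + 1), , drop = FALSE]
  }
  path_pts
}

# extend the stem path downward along its end tangent to the cloud's min Y
.anchor_path_base <- function(path_pts, min_y) {
  if (nrow(path_pts) < 2) return(path_pts)
  a <- path_pts[1, ]; b <- path_pts[2, ]
  t <- a - b
  nt <- sqrt(sum(t^2))
  if (nt == 0) return(path_pts)
  t <- t / nt
  if (t[2] >= -0.3) return(path_pts)        # end tangent not pointing down
  if (a[2] <= min_y + 1e-9) return(path_pts)
  base <- a + t * ((min_y - a[2]) / t[2])
  rbind(base, path_pts)
}

#' Run the full phenotyping pipeline on a plant cloud
#'
#' Executes SOR filtering, iterative density-weighted voxel-centroid
#' skeletonization, MST construction with node typing, principal-direction
#' analysis, highest-junction and root selection, Dijkstra path extraction,
#' cubic-spline stem-curve smoothing, radius-search stem labeling, VCCS +
#' LCCP + adaptive K-means++ leaf segmentation, and trait computation.
#'
#' @param cloud a \linkS4class{PlantCloud}, or a path to a PLY/PCD file
#' @param config a \code{\link{pipelineConfig}}
#' @param keep_intermediate return intermediate objects (skeleton, graph,
#'   curve, masks, segmentation, meshes) alongside the report
#' @return a \linkS4class{TraitReport}; with \code{keep_intermediate = TRUE},
#'   a list \code{(report, intermediate)}
#' @export
#' @examples
#' pl <- generatePlant(plantSpec(stem_height = 0.3, n_leaves = 5,
#'                               points_per_m2 = 4e5, outlier_count = 50,
#'                               seed = 11))
#' \donttest{
#' rep <- runPipeline(pl$cloud, pipelineConfig(sor = sorConfig(30, 1.1),
#'                                             stem_radius = 0.002))
#' rep
#' }
runPipeline <- function(cloud, config = pipelineConfig(),
                        keep_intermediate = FALSE) {
  if (is.character(cloud)) cloud <- readCloud(cloud)
  stopifnot(is(cloud, "PlantCloud"), inherits(config, "PipelineConfig"))
  log <- list(input_points = nPoints(cloud))

  ## 1. preprocess
  f <- sorFilter(cloud, config$sor)
  clean <- f$cloud
  log$sor_removed <- length(f$removed)
  log$kept_points <- nPoints(clean)

  ## 2. skeletonize
  skel <- skeletonize(clean, L0 = config$L0, theta = config$theta,
                      n_iter = config$n_iter)
  log$skeleton_points <- nPoints(skel)

  ## 3. stem extraction
  graph <- buildMST(coords(skel))
  line <- principalDirection(coords(skel))
  jn <- selectHighestJunction(graph, line, config$junction_radius)
  rt <- rootNode(graph, line, config$junction_radius)
  path <- treePath(graph, jn, rt)
  path_pts <- graph@nodes[rev(path), , drop = FALSE]  # root -> junction
  if (!is.null(config$path_max_turn))
    path_pts <- .despike_path(path_pts, config$path_max_turn)
  if (isTRUE(config$anchor_base))
    path_pts <- .anchor_path_base(path_pts, min(coords(clean)[, 2]))
  curve <- smoothCurve(path_pts, step = config$curve_step)
  label_radius <- if (!is.null(config$stem_radius))
    config$stem_label_factor * config$stem_radius + config$stem_label_slack
  else config$stem_label_default
  stem_mask <- labelStem(clean, curve, label_radius)
  log$stem_points <- sum(stem_mask)

  ## 4. leaf segmentation
  leaf_cloud <- plantCloud(coords(clean)[!stem_mask, , drop = FALSE],
                           labels = if (length(clean@labels))
                             clean@labels[!stem_mask] else character(0))
  km <- config$kmeans
  km$seed <- config$seed
  empty_seg <- function(n) new("LeafSegmentation",
    labels = integer(n), sizes = integer(0), meanSize = NA_real_,
    kTable = data.frame())
  seg <- if (nPoints(leaf_cloud) > config$lccp$min_cluster_points)
    tryCatch(segmentLeaves(leaf_cloud, config$vccs, config$lccp, km),
             error = function(e) {
               log$segmentation_error <<- conditionMessage(e)
               empty_seg(nPoints(leaf_cloud))
             })
  else empty_seg(nPoints(leaf_cloud))
  n_leaves <- length(unique(seg@labels[seg@labels > 0]))
  log$leaf_clusters <- n_leaves

  ## 5. traits
  H <- plantHeight(clean)
  SL <- stemLength(curve)
  stem_cloud <- coords(clean)[stem_mask, , drop = FALSE]
  SD <- tryCatch(suppressWarnings(
    stemDiameter(stem_cloud, config$slice_start, config$slice_spacing,
                 config$n_slices, config$slice_thickness)),
    error = function(e) { log$diameter_error <<- conditionMessage(e); NA_real_ })
  areas <- numeric(n_leaves)
  meshes <- vector("list", n_leaves)
  lp <- coords(leaf_cloud)
  for (k in seq_len(n_leaves)) {
    pts <- lp[seg@labels == k, , drop = FALSE]
    dn <- .planar_downsample(pts, config$mesh_voxel)
    ar <- tryCatch({
      mesh <- triangulateLeaf(dn, mu = config$mesh_mu,
                              max_edge = config$mesh_max_edge)
      mesh <- fillHoles(mesh)
      meshes[[k]] <- mesh
      leafArea(mesh, double_sided = config$double_sided)
    }, error = function(e) NA_real_)
    areas[k] <- ar
  }

  report <- new("TraitReport", height = H, stemLength = SL,
                stemDiameter = SD, leafAreas = areas,
                parameters = unclass(config), log = log)
  if (!keep_intermediate) return(report)
  list(report = report,
       intermediate = list(clean = clean, removed = f$removed, skeleton = skel,
                           graph = graph, line = line, junction = jn,
                           root = rt, path = path, curve = curve,
                           stem_mask = stem_mask, leaf_cloud = leaf_cloud,
                           segmentation = seg, meshes = meshes))
}

#' Write a trait report to CSV and JSON
#'
#' @param report a \linkS4class{TraitReport}
#' @param dir output directory
#' @return invisibly, the file paths
#' @export
writeTraitReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, "traits.csv")
  js <- file.path(dir, "traits.json")
  df <- data.frame(trait = c("plant_height_m", "stem_length_m",
                             "stem_diameter_m",
                             paste0("leaf_area_m2_", seq_along(report@leafAreas))),
                   value = c(report@height, report@stemLength,
                             report@stemDiameter, report@leafAreas))
  utils::write.csv(df, csv, row.names = FALSE)
  jsonlite::write_json(list(plant_height_m = report@height,
                            stem_length_m = report@stemLength,
                            stem_diameter_m = report@stemDiameter,
                            leaf_areas_m2 = report@leafAreas,
                            log = report@log),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
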