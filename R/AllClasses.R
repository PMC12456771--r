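#' @useDynLib skelphen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats dist splinefun approx runif rnorm
#' @importFrom utils head tail
#' @importFrom tools file_ext
NULL

#' PlantCloud: a metric 3D point cloud
#'
#' The universal currency of the pipeline: an n x 3 matrix of XYZ coordinates
#' in meters (gravity along +Y), with optional per-point character labels
#' (\code{"stem"}, \code{"leaf_<k>"}, \code{"outlier"}, or \code{NA}) and a
#' free-form metadata list carrying provenance (e.g. skeleton iteration
#' weights).
#'
#' @slot points numeric matrix (n x 3), columns x/y/z in meters.
#' @slot labels character vector of length n, or length 0 if unlabeled.
#' @slot metadata list of provenance entries.
#' @export
setClass("PlantCloud",
  representation(points = "matrix", labels = "character", metadata = "list"),
  prototype(points = matrix(numeric(0), 0, 3), labels = character(0),
            metadata = list()))

setValidity("PlantCloud", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3)
    return("points must be a numeric matrix with 3 columns")
  if (anyNA(p)) return("points must not contain NA")
  if (length(object@labels) && length(object@labels) != nrow(p))
    return("labels must be empty or have one entry per point")
  TRUE
})

#' SkeletonGraph: minimum spanning tree over skeleton points
#'
#' @slot nodes numeric matrix (n x 3) of skeleton point coordinates (m).
#' @slot edges integer matrix (n-1 x 2) of 1-based node indices.
#' @slot weights numeric edge lengths (m).
#' @slot nodeClass character, one of TIP/INTERNAL/JUNCTION per node.
#' @export
setClass("SkeletonGraph",
  representation(nodes = "matrix", edges = "matrix", weights = "numeric",
                 nodeClass = "character"))

setValidity("SkeletonGraph", function(object) {
  n <- nrow(object@nodes)
  e <- object@edges
  if (ncol(object@nodes) != 3) return("nodes must have 3 columns")
  if (n >= 2 && nrow(e) != n - 1)
    return("a spanning tree on n nodes must have n-1 edges")
  if (nrow(e) && (min(e) < 1 || max(e) > n))
    return("edge indices out of range")
  if (length(object@weights) != nrow(e))
    return("one weight per edge required")
  if (length(object@nodeClass) &&
      !all(object@nodeClass %in% c("TIP", "INTERNAL", "JUNCTION")))
    return("nodeClass entries must be TIP, INTERNAL or JUNCTION")
  TRUE
})

#' StemCurve: smoothed stem axis polyline
#'
#' Ordered root-to-top samples of the spline-smoothed stem axis at a fixed
#' nominal arc step, with cumulative arc length.
#'
#' @slot samples numeric matrix (m x 3), ordered root -> top.
#' @slot arcLength numeric vector of cumulative arc length (m), starting at 0.
#' @slot step numeric, nominal resampling step (m).
#' @export
setClass("StemCurve",
  representation(samples = "matrix", arcLength = "numeric", step = "numeric"))

setValidity("StemCurve", function(object) {
  s <- object@samples
  if (ncol(s) != 3) return("samples must have 3 columns")
  if (nrow(s) < 2) return("a curve needs at least 2 samples")
  if (length(object@arcLength) != nrow(s))
    return("arcLength must have one entry per sample")
  if (is.unsorted(object@arcLength)) return("arcLength must be non-decreasing")
  seg <- sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  if (length(object@step) == 1 && any(seg > 2 * object@step + 1e-12))
    return("consecutive sample spacing exceeds twice the nominal step")
  TRUE
})

#' LeafSegmentation: per-point leaf instance labels
#'
#' @slot labels integer vector, one per input point; 0 marks points dropped by
#'   the minimum-cluster-size filter, positive values are compact leaf ids.
#' @slot sizes integer vector of retained coarse-cluster sizes (points).
#' @slot meanSize numeric, mean coarse cluster size used by the adaptive-K rule.
#' @slot kTable data.frame with one row per anomalous coarse cluster
#'   (columns: cluster, size, k).
#' @export
setClass("LeafSegmentation",
  representation(labels = "integer", sizes = "integer", meanSize = "numeric",
                 kTable = "data.frame"))

setValidity("LeafSegmentation", function(object) {
  if (any(object@labels < 0)) return("labels must be >= 0")
  TRUE
})

#' TraitReport: the four phenotypic parameters
#'
#' @slot height numeric, plant height (m).
#' @slot stemLength numeric, stem arc length root to highest junction (m).
#' @slot stemDiameter numeric, ellipse-slice stem diameter (m).
#' @slot leafAreas numeric vector of per-leaf areas (m^2).
#' @slot parameters list of the pipeline parameters used.
#' @slot log list of per-stage diagnostics (point counts, notes).
#' @export
setClass("TraitReport",
  representation(height = "numeric", stemLength = "numeric",
                 stemDiameter = "numeric", leafAreas = "numeric",
                 parameters = "list", log = "list"))

setValidity("TraitReport", function(object) {
  vals <- c(object@height, object@stemLength, object@stemDiameter,
            object@leafAreas)
  if (any(is.finite(vals) & vals < 0)) return("trait values must be >= 0")
  TRUE
})
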