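#' Number of points in a cloud
#' @param x a PlantCloud
#' @return integer point count
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' Coordinates of a cloud, curve or graph
#' @param x a PlantCloud, StemCurve or SkeletonGraph
#' @return numeric matrix of XYZ coordinates (meters)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Per-point labels
#' @param x a PlantCloud or LeafSegmentation
#' @return labels (character for clouds, integer for segmentations)
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "PlantCloud", function(x) nrow(x@points))

#' @rdname coords
#' @export
setMethod("coords", "PlantCloud", function(x) x@points)

#' @rdname coords
#' @export
setMethod("coords", "StemCurve", function(x) x@samples)

#' @rdname coords
#' @export
setMethod("coords", "SkeletonGraph", function(x) x@nodes)

#' @rdname pointLabels
#' @export
setMethod("pointLabels", "PlantCloud", function(x) {
  if (length(x@labels)) x@labels else rep(NA_character_, nPoints(x))
})

#' @rdname pointLabels
#' @export
setMethod("pointLabels", "LeafSegmentation", function(x) x@labels)

setMethod("show", "PlantCloud", function(object) {
  cat(sprintf("PlantCloud with %d points", nPoints(object)))
  if (nPoints(object)) {
    bb <- apply(object@points, 2, range)
    cat(sprintf(" | bbox [%.3f,%.3f]x[%.3f,%.3f]x[%.3f,%.3f] m",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  if (length(object@labels)) {
    tb <- table(object@labels, useNA = "no")
    cat(sprintf("\n  labels: %s",
                paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  cat("\n")
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d nodes, %d edges", nrow(object@nodes),
              nrow(object@edges)))
  if (length(object@nodeClass)) {
    tb <- table(object@nodeClass)
    cat(sprintf(" (%s)", paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
  }
  cat("\n")
})

setMethod("show", "StemCurve", function(object) {
  cat(sprintf("StemCurve: %d samples, arc length %.4f m (step %.4g m)\n",
              nrow(object@samples), max(object@arcLength), object@step))
})

setMethod("show", "LeafSegmentation", function(object) {
  k <- length(unique(object@labels[object@labels > 0]))
  cat(sprintf("LeafSegmentation: %d points, %d leaves (%d dropped)\n",
              length(object@labels), k, sum(object@labels == 0)))
})

setMethod("show", "TraitReport", function(object) {
  cat("TraitReport\n")
  cat(sprintf("  plant height : %.4f m\n", object@height))
  cat(sprintf("  stem length  : %.4f m\n", object@stemLength))
  cat(sprintf("  stem diameter: %.5f m\n", object@stemDiameter))
  cat(sprintf("  leaf areas   : %d leaves, total %.6f m^2\n",
              length(object@leafAreas), sum(object@leafAreas)))
})

#' Construct a PlantCloud
#'
#' @param points n x 3 numeric matrix of XYZ coordinates in meters.
#' @param labels optional character labels, one per point.
#' @param metadata optional list of provenance entries.
#' @return a \linkS4class{PlantCloud}
#' @export
#' @examples
#' pc <- plantCloud(matrix(rnorm(30), 10, 3))
#' nPoints(pc)
plantCloud <- function(points, labels = character(0), metadata = list()) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  new("PlantCloud", points = points, labels = as.character(labels),
      metadata = metadata)
}
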