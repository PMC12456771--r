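# Stem identification on the skeleton: Euclidean minimum spanning tree
# (Kruskal with union-find), degree-based node typing, PCA principal line,
# highest-junction selection near that line, Dijkstra root-to-junction path,
# cubic-spline smoothing and radius-based stem labeling of the full cloud.

#' Build the Euclidean minimum spanning tree over skeleton points
#'
#' Kruskal's algorithm on the complete Euclidean graph, with ties broken by
#' lexicographic node-index order for determinism. For large node sets a
#' k-nearest-neighbour candidate graph can be used instead; connectivity is
#' checked and the method falls back to the complete graph if the kNN graph
#' is disconnected.
#'
#' @param points n x 3 matrix or \linkS4class{PlantCloud} of skeleton points
#' @param method \code{"complete"} (exact, default) or \code{"knn"}
#' @param k neighbour count for the kNN candidate graph
#' @return a \linkS4class{SkeletonGraph} with node classes filled in
#' @export
buildMST <- function(points, method = c("complete", "knn"), k = 10L) {
  p <- if (is(points, "PlantCloud")) coords(points) else as.matrix(points)
  n <- nrow(p)
  if (n < 2) stop("an MST needs at least 2 points")
  method <- match.arg(method)
  edges <- NULL
  if (method == "knn" && n > k + 1) {
    nn <- cpp_knn(p, p, as.integer(k) + 1L)
    i <- rep(seq_len(n), k)
    j <- as.vector(nn$index[, -1])
    a <- pmin(i, j); b <- pmax(i, j)
    keep <- !duplicated(cbind(a, b))
    edges <- cbind(a[keep], b[keep])
    w <- sqrt(rowSums((p[edges[, 1], , drop = FALSE] -
                       p[edges[, 2], , drop = FALSE])^2))
  }
  if (is.null(edges)) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    edges <- cbind(idx[, "row"], idx[, "col"])
    w <- sqrt(rowSums((p[edges[, 1], , drop = FALSE] -
                       p[edges[, 2], , drop = FALSE])^2))
  }
  ord <- order(w, edges[, 1], edges[, 2])
  uf <- seq_len(n)  # union-find parent array, path compression in find()
  find <- function(i) {
    root <- i
    while (uf[root] != root) root <- uf[root]
    while (uf[i] != root) { nxt <- uf[i]; uf[i] <<- root; i <- nxt }
    root
  }
  sel <- integer(n - 1)
  nsel <- 0L
  for (e in ord) {
    ra <- find(edges[e, 1])
    rb <- find(edges[e, 2])
    if (ra != rb) {
      uf[min(ra, rb)] <- max(ra, rb)
      nsel <- nsel + 1L
      sel[nsel] <- e
      if (nsel == n - 1L) break
    }
  }
  if (nsel < n - 1L) {
    if (method == "knn") return(buildMST(p, method = "complete"))
    stop("internal error: complete graph failed to connect")  # nocov
  }
  g <- new("SkeletonGraph", nodes = unname(p),
           edges = unname(edges[sel, , drop = FALSE]),
           weights = unname(w[sel]), nodeClass = character(0))
  g@nodeClass <- classifyNodes(g)
  g
}

#' Classify skeleton-graph nodes by degree
#'
#' TIP: degree <= 1 (leaf tips); INTERNAL: degree 2 (stem interior);
#' JUNCTION: degree >= 3 (branching points).
#'
#' @param graph a \linkS4class{SkeletonGraph}
#' @return character vector of classes, one per node
#' @export
classifyNodes <- function(graph) {
  stopifnot(is(graph, "SkeletonGraph"))
  n <- nrow(graph@nodes)
  deg <- tabulate(c(graph@edges), nbins = n)
  cls <- rep("INTERNAL", n)
  cls[deg <= 1] <- "TIP"
  cls[deg >= 3] <- "JUNCTION"
  cls
}

#' Principal structural direction of a point set
#'
#' Leading eigenvector of the coordinate covariance, sign-flipped so the
#' direction has a non-negative Y component, anchored at the centroid.
#'
#' @param points n x 3 matrix or \linkS4class{PlantCloud}
#' @return list of class \code{"PrincipalLine"}: unit \code{direction},
#'   \code{anchor} (centroid), and the eigenvalues.
#' @export
principalDirection <- function(points) {
  p <- if (is(points, "PlantCloud")) coords(points) else as.matrix(points)
  if (nrow(p) < 2) stop("need at least 2 points")
  ctr <- colMeans(p)
  q <- sweep(p, 2, ctr)
  if (all(abs(q) < 1e-15)) stop("all points identical; no principal direction")
  ev <- eigen(crossprod(q) / nrow(p), symmetric = TRUE)
  d <- ev$vectors[, 1]
  if (d[2] < 0) d <- -d
  structure(list(direction = d / sqrt(sum(d^2)), anchor = ctr,
                 eigenvalues = ev$values), class = "PrincipalLine")
}

# perpendicular distance of points to a principal line
.line_dist <- function(p, line) {
  q <- sweep(as.matrix(p), 2, line$anchor)
  t <- drop(q %*% line$direction)
  sqrt(pmax(0, rowSums(q^2) - t^2))
}

#' Select the highest junction node near the principal line
#'
#' Among JUNCTION nodes whose perpendicular distance to the principal line is
#' at most \code{radius} (default 2 cm), the node with maximal Y is returned.
#' If no junction qualifies (unbranched plant), the qualifying node of any
#' class with maximal Y is returned with a warning.
#'
#' @param graph a classified \linkS4class{SkeletonGraph}
#' @param line a \code{\link{principalDirection}} result
#' @param radius line-distance gate in meters
#' @return 1-based node index
#' @export
selectHighestJunction <- function(graph, line, radius = 0.02) {
  stopifnot(is(graph, "SkeletonGraph"), radius > 0)
  d <- .line_dist(graph@nodes, line)
  near <- which(d <= radius)
  if (!length(near))
    stop("no skeleton node within ", radius,
         " m of the principal line; increase the junction radius")
  cls <- if (length(graph@nodeClass)) graph@nodeClass else classifyNodes(graph)
  cand <- near[cls[near] == "JUNCTION"]
  if (!length(cand)) {
    warning("no junction near the principal line; falling back to the ",
            "highest near-line node (unbranched plant?)")
    cand <- near
  }
  cand[which.max(graph@nodes[cand, 2])]
}

#' Root node: lowest skeleton node near the principal line
#'
#' @inheritParams selectHighestJunction
#' @return 1-based node index
#' @export
rootNode <- function(graph, line, radius = 0.02) {
  stopifnot(is(graph, "SkeletonGraph"), radius > 0)
  d <- .line_dist(graph@nodes, line)
  near <- which(d <= radius)
  if (!length(near))
    stop("no skeleton node within ", radius,
         " m of the principal line; increase the junction radius")
  near[which.min(graph@nodes[near, 2])]
}

#' Shortest path between two nodes of the skeleton tree
#'
#' Dijkstra's algorithm on the edge-weighted graph. On a tree this equals the
#' unique simple path, which is asserted.
#'
#' @param graph a \linkS4class{SkeletonGraph}
#' @param src,dst 1-based node indices
#' @return integer vector of node indices from \code{src} to \code{dst}
#' @export
treePath <- function(graph, src, dst) {
  stopifnot(is(graph, "SkeletonGraph"))
  n <- nrow(graph@nodes)
  stopifnot(src >= 1, src <= n, dst >= 1, dst <= n)
  src <- as.integer(src); dst <- as.integer(dst)
  if (src == dst) return(src)
  adj <- vector("list", n)
  e <- graph@edges; w <- graph@weights
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- rbind(adj[[e[i, 1]]], c(e[i, 2], w[i]))
    adj[[e[i, 2]]] <- rbind(adj[[e[i, 2]]], c(e[i, 1], w[i]))
  }
  dist <- rep(Inf, n); dist[src] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  for (iter in seq_len(n)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    if (u == dst) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      alt <- dist[u] + nb[r, 2]
      if (alt < dist[v]) { dist[v] <- alt; prev[v] <- u }
    }
  }
  if (!is.finite(dist[dst])) stop("nodes are not connected")
  path <- dst
  while (path[1] != src) path <- c(prev[path[1]], path)
  path <- as.integer(path)
  # sanity: on a tree the Dijkstra path is the unique simple path
  stopifnot(!anyNA(path), length(unique(path)) == length(path))
  path
}

#' Smooth a skeleton path into a stem curve
#'
#' Natural cubic spline through the path points, parameterized by cumulative
#' chord length and resampled at a fixed arc step (default 1 mm). Two-point
#' paths degrade to a straight segment. Duplicate consecutive points are
#' deduplicated with a warning.
#'
#' @param path_points ordered k x 3 matrix of path node coordinates
#' @param step resampling arc step in meters
#' @return a \linkS4class{StemCurve}
#' @export
smoothCurve <- function(path_points, step = 0.001) {
  p <- as.matrix(path_points)
  if (nrow(p) >= 2) {
    dup <- c(FALSE, rowSums(abs(diff(p))) < 1e-12)
    if (any(dup)) {
      warning("duplicate consecutive path points removed")
      p <- p[!dup, , drop = FALSE]
    }
  }
  if (nrow(p) < 2) stop("need at least 2 distinct path points")
  chord <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  if (nrow(p) == 2) {
    m <- max(2L, ceiling(chord[2] / step) + 1L)
    t <- seq(0, chord[2], length.out = m)
    samples <- cbind(approx(chord, p[, 1], t)$y, approx(chord, p[, 2], t)$y,
                     approx(chord, p[, 3], t)$y)
    return(new("StemCurve", samples = samples, arcLength = t, step = step))
  }
  fx <- splinefun(chord, p[, 1], method = "natural")
  fy <- splinefun(chord, p[, 2], method = "natural")
  fz <- splinefun(chord, p[, 3], method = "natural")
  # dense evaluation, then uniform-arc resampling
  tfine <- seq(0, max(chord), length.out = max(200L, 8L * ceiling(max(chord) / step)))
  dense <- cbind(fx(tfine), fy(tfine), fz(tfine))
  arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  total <- max(arc)
  m <- max(2L, ceiling(total / step) + 1L)
  s <- seq(0, total, length.out = m)
  ti <- approx(arc, tfine, s)$y
  samples <- cbind(fx(ti), fy(ti), fz(ti))
  seg <- sqrt(rowSums(diff(samples)^2))
  new("StemCurve", samples = samples, arcLength = c(0, cumsum(seg)),
      step = step)
}

#' Label stem points in the full cloud by distance to the stem curve
#'
#' A point is labeled stem iff its exact distance to the nearest curve
#' segment (point-to-segment, not point-to-sample) is at most \code{radius}.
#' A kd-tree over curve samples prunes candidates; confirmation is exact.
#'
#' @param cloud a \linkS4class{PlantCloud}
#' @param curve a \linkS4class{StemCurve}
#' @param radius search radius in meters; conventionally set from the
#'   manually measured stem diameter (see \code{\link{pipelineConfig}}).
#' @return logical vector, TRUE for stem points
#' @export
labelStem <- function(cloud, curve, radius) {
  stopifnot(is(cloud, "PlantCloud"), is(curve, "StemCurve"), radius > 0)
  if (nrow(curve@samples) < 2) stop("empty or degenerate stem curve")
  d <- cpp_polyline_dist(coords(cloud), curve@samples, radius,
                         max(curve@step, max(diff(curve@arcLength))))
  d <= radius
}
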