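# PLY / PCD point-cloud I/O. Only the subset of the formats that point-cloud
# phenotyping tools exchange is supported: xyz vertices (float/double) plus an
# optional integer "label" scalar; ascii and binary-little-endian PLY on read,
# ascii on write; ascii PCD.

#' Write a point cloud to an ascii PLY file
#'
#' @param cloud a \linkS4class{PlantCloud}
#' @param path output file path
#' @param digits significant digits for coordinates
#' @return invisibly, \code{path}
#' @export
writePLY <- function(cloud, path, digits = 9) {
  stopifnot(is(cloud, "PlantCloud"))
  p <- coords(cloud)
  has_lab <- length(cloud@labels) > 0
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           "comment produced by skelphen",
           sprintf("element vertex %d", nrow(p)),
           "property double x", "property double y", "property double z")
  if (has_lab) hdr <- c(hdr, "property int label")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  if (nrow(p)) {
    body <- apply(signif(p, digits), 1, paste, collapse = " ")
    if (has_lab) body <- paste(body, .encode_labels(cloud@labels))
    writeLines(body, con)
  }
  invisible(path)
}

# labels <-> integer codes stored in PLY: 0 stem, -1 outlier, -9 NA, k>0 leaf_k
.encode_labels <- function(lab) {
  code <- rep(-9L, length(lab))
  code[lab %in% "stem"] <- 0L
  code[lab %in% "outlier"] <- -1L
  isleaf <- grepl("^leaf_[0-9]+$", lab)
  code[isleaf] <- as.integer(sub("^leaf_", "", lab[isleaf]))
  code
}

.decode_labels <- function(code) {
  lab <- rep(NA_character_, length(code))
  lab[code == 0L] <- "stem"
  lab[code == -1L] <- "outlier"
  lab[code > 0L] <- paste0("leaf_", code[code > 0L])
  lab
}

#' Read a PLY point cloud (ascii or binary little-endian)
#'
#' @param path file path
#' @return a \linkS4class{PlantCloud}; a \code{label} property, when present,
#'   is decoded into per-point labels.
#' @export
readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop("not a PLY file: ", path)
  fmt <- NULL; nvert <- NULL
  props <- character(0); ptypes <- character(0)
  in_vertex <- FALSE
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop("unterminated PLY header in ", path)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      props <- c(props, tok[length(tok)])
      ptypes <- c(ptypes, tok[2])
    } else if (tok[1] == "end_header") break
  }
  if (is.null(nvert)) stop("PLY file has no vertex element: ", path)
  need <- match(c("x", "y", "z"), props)
  if (anyNA(need)) stop("PLY vertex element lacks x/y/z: ", path)
  if (identical(fmt, "ascii")) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))][seq_len(nvert)]
    vals <- matrix(as.numeric(unlist(strsplit(trimws(txt), "\\s+"))),
                   nrow = nvert, byrow = TRUE)
  } else if (identical(fmt, "binary_little_endian")) {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    sz <- sizes[ptypes]
    if (anyNA(sz)) stop("unsupported PLY property type in ", path)
    vals <- matrix(NA_real_, nvert, length(props))
    for (i in seq_len(nvert)) {
      for (j in seq_along(props)) {
        tp <- ptypes[j]
        vals[i, j] <- if (tp %in% c("float", "float32", "double", "float64")) {
          readBin(con, "double", 1, size = sz[j], endian = "little")
        } else {
          readBin(con, "integer", 1, size = sz[j], endian = "little",
                  signed = !(tp %in% c("uchar", "uint8", "ushort", "uint16")))
        }
      }
    }
  } else stop("unsupported PLY format '", fmt, "' in ", path)
  pts <- vals[, need, drop = FALSE]
  lab <- character(0)
  li <- match("label", props)
  if (!is.na(li)) lab <- .decode_labels(as.integer(vals[, li]))
  plantCloud(pts, labels = lab)
}

#' Write a point cloud to an ascii PCD file
#'
#' @inheritParams writePLY
#' @return invisibly, \code{path}
#' @export
writePCD <- function(cloud, path, digits = 9) {
  stopifnot(is(cloud, "PlantCloud"))
  p <- coords(cloud)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# .PCD v0.7 - Point Cloud Data file format",
               "VERSION 0.7", "FIELDS x y z", "SIZE 8 8 8", "TYPE F F F",
               "COUNT 1 1 1", sprintf("WIDTH %d", nrow(p)), "HEIGHT 1",
               "VIEWPOINT 0 0 0 1 0 0 0", sprintf("POINTS %d", nrow(p)),
               "DATA ascii"), con)
  if (nrow(p)) writeLines(apply(signif(p, digits), 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an ascii PCD point cloud
#'
#' @param path file path
#' @return a \linkS4class{PlantCloud}
#' @export
readPCD <- function(path) {
  lns <- readLines(path)
  lns <- lns[!grepl("^\\s*#", lns)]
  hdr_end <- grep("^DATA\\b", lns)[1]
  if (is.na(hdr_end)) stop("not a PCD file: ", path)
  if (!grepl("ascii", lns[hdr_end])) stop("only ascii PCD is supported: ", path)
  fields <- strsplit(sub("^FIELDS\\s+", "", grep("^FIELDS", lns, value = TRUE)[1]),
                     "\\s+")[[1]]
  need <- match(c("x", "y", "z"), fields)
  if (anyNA(need)) stop("PCD file lacks x/y/z fields: ", path)
  body <- lns[(hdr_end + 1):length(lns)]
  body <- body[nzchar(trimws(body))]
  vals <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                 nrow = length(body), byrow = TRUE)
  plantCloud(vals[, need, drop = FALSE])
}

#' Read a point cloud, dispatching on file extension
#' @param path a .ply or .pcd file
#' @return a \linkS4class{PlantCloud}
#' @export
readCloud <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext, ply = readPLY(path), pcd = readPCD(path),
         stop("unsupported point-cloud format: .", ext))
}
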