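# Mesh and point-cloud file formats (STL binary/ASCII, PLY ASCII, XYZ text).
# Units are mm throughout.

#' Write a triangle mesh as STL
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output file.
#' @param binary write binary STL (default) or ASCII.
#' @export
writeSTL <- function(mesh, path, binary = TRUE) {
  v <- mesh@vertices; f <- mesh@faces
  n <- faceNormals(mesh)
  m <- nrow(f)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(m), con, size = 4, endian = "little")
    tri <- cbind(n, v[f[, 1L], , drop = FALSE], v[f[, 2L], , drop = FALSE],
                 v[f[, 3L], , drop = FALSE])
    dat <- as.vector(t(tri))
    # interleave the 2-byte attribute count after every 12 floats
    for (i in seq_len(m)) {
      writeBin(dat[(12 * (i - 1) + 1):(12 * i)], con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(m)) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII, auto-detected)
#'
#' Coincident vertices are welded so connectivity is restored.
#' @param path STL file.
#' @return a \linkS4class{TriangleMesh}.
#' @export
readSTL <- function(path) {
  hdr <- readBin(path, "raw", n = 5L)
  isAscii <- identical(rawToChar(hdr), "solid") && {
    txt <- readLines(path, n = 10L, warn = FALSE)
    any(grepl("facet", txt))
  }
  if (isAscii) {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    m <- readBin(con, "integer", n = 1L, size = 4, endian = "little")
    V <- matrix(NA_real_, 3L * m, 3L)
    for (i in seq_len(m)) {
      vals <- readBin(con, "numeric", n = 12L, size = 4, endian = "little")
      readBin(con, "integer", n = 1L, size = 2, endian = "little")
      V[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    }
  }
  m <- nrow(V) / 3L
  key <- paste(round(V[, 1], 9), round(V[, 2], 9), round(V[, 3], 9))
  uid <- match(key, unique(key))
  Vu <- V[!duplicated(key), , drop = FALSE]
  F <- matrix(uid, ncol = 3L, byrow = TRUE)
  triangleMesh(Vu, F)
}

#' Write a point cloud as XYZ text (x y z [nx ny nz])
#' @param cloud a \linkS4class{PointCloud}.
#' @param path output file.
#' @export
writeXYZ <- function(cloud, path) {
  M <- cloud@positions
  if (!is.null(cloud@normals)) M <- cbind(M, cloud@normals)
  utils::write.table(M, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an XYZ text point cloud
#' @param path file with 3 (positions) or 6 (+normals) columns.
#' @export
readXYZ <- function(path) {
  M <- as.matrix(utils::read.table(path))
  dimnames(M) <- NULL
  if (ncol(M) >= 6) {
    nrm <- M[, 4:6, drop = FALSE]
    nrm <- nrm / sqrt(rowSums(nrm^2))
    pointCloud(M[, 1:3, drop = FALSE], normals = nrm)
  } else pointCloud(M[, 1:3, drop = FALSE])
}

#' Write a mesh as ASCII PLY
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output file.
#' @export
writePLY <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path PLY file (ascii 1.0, vertex + face elements).
#' @export
readPLY <- function(path) {
  txt <- readLines(path, warn = FALSE)
  endh <- which(txt == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", txt, value = TRUE)[1]))
  vlines <- txt[(endh + 1):(endh + nv)]
  V <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(x) as.numeric(x[1:3])))
  flines <- txt[(endh + nv + 1):(endh + nv + nf)]
  F <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(x) as.integer(x[2:4]) + 1L))
  triangleMesh(V, F)
}
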