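#' @name accessors
#' @title Accessors for the core data classes
#' @description Slot access goes through these functions rather than
#'   \code{@}: \code{positions}, \code{normals}, \code{pointLabels},
#'   \code{vertices}, \code{faces}, \code{intensities}, \code{spacing},
#'   \code{origin}, \code{voxelLabels}, \code{phi}, \code{deltaN},
#'   \code{toothId}, \code{sliceIndices}, \code{sliceContours},
#'   \code{tauOpt}.
NULL

#' @rdname accessors
#' @param x object.
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setMethod("positions", "PointCloud", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("normals", function(x) standardGeneric("normals"))
#' @rdname accessors
#' @export
setMethod("normals", "PointCloud", function(x) x@normals)

#' @rdname accessors
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))
#' @rdname accessors
#' @export
setMethod("pointLabels", "PointCloud", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("pointTags", function(x) standardGeneric("pointTags"))
#' @rdname accessors
#' @export
setMethod("pointTags", "PointCloud", function(x) x@tags)

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "VoxelVolume", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setMethod("spacing", "VoxelVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "LevelSetField", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setMethod("origin", "VoxelVolume", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("voxelLabels", function(x) standardGeneric("voxelLabels"))
#' @rdname accessors
#' @export
setMethod("voxelLabels", "VoxelVolume", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("phi", function(x) standardGeneric("phi"))
#' @rdname accessors
#' @export
setMethod("phi", "LevelSetField", function(x) x@phi)

#' @rdname accessors
#' @export
setGeneric("deltaN", function(x) standardGeneric("deltaN"))
#' @rdname accessors
#' @export
setMethod("deltaN", "CurvatureField", function(x) x@delta)

#' @rdname accessors
#' @export
setGeneric("toothId", function(x) standardGeneric("toothId"))
#' @rdname accessors
#' @export
setMethod("toothId", "SliceContourStack", function(x) x@toothId)
#' @rdname accessors
#' @export
setMethod("toothId", "ToothModel", function(x) x@toothId)
#' @rdname accessors
#' @export
setMethod("toothId", "MarginLine", function(x) x@toothId)

#' @rdname accessors
#' @export
setGeneric("sliceIndices", function(x) standardGeneric("sliceIndices"))
#' @rdname accessors
#' @export
setMethod("sliceIndices", "SliceContourStack", function(x) x@sliceIndices)

#' @rdname accessors
#' @export
setGeneric("sliceContours", function(x) standardGeneric("sliceContours"))
#' @rdname accessors
#' @export
setMethod("sliceContours", "SliceContourStack", function(x) x@contours)

#' @rdname accessors
#' @export
setGeneric("tauOpt", function(x) standardGeneric("tauOpt"))
#' @rdname accessors
#' @export
setMethod("tauOpt", "ThresholdSweepResult", function(x) x@tauOpt)

#' Construct a point cloud
#' @param positions N x 3 matrix, mm.
#' @param normals optional N x 3 unit normals.
#' @param labels,tags optional per-point annotations.
#' @param metadata list.
#' @export
pointCloud <- function(positions, normals = NULL, labels = NULL, tags = NULL,
                       metadata = list()) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  if (!is.null(normals)) dimnames(normals) <- NULL
  new("PointCloud", positions = positions, normals = normals,
      labels = unname(labels), tags = unname(tags), metadata = metadata)
}

#' Valid ISO 3950 (FDI) tooth codes
#'
#' Two-digit codes: quadrant 1-4 (permanent) or 5-8 (deciduous), position 1-8
#' (1-5 deciduous).
#' @param id character code(s).
#' @export
isValidToothId <- function(id) {
  ok <- grepl("^[1-8][1-8]$", id)
  q <- as.integer(substr(id, 1, 1)); p <- as.integer(substr(id, 2, 2))
  ok & ifelse(q >= 5, p <= 5, TRUE)
}
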