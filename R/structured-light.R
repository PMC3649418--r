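# Structured-light measurement: temporal binary stripe coding, per-pixel
# decoding, ray-plane triangulation and turntable view composition.

#' Generate a binary stripe pattern set
#'
#' n patterns of vertical stripes whose period is halved at each temporal
#' step (pattern 1 = most significant bit). Reading the bright/dark state of
#' a pixel across the stack MSB-first yields its stripe code; the coding
#' provides \code{2^n - 1} encoded line boundaries and an encoded point
#' budget of \code{lh * lv}.
#'
#' @param n number of patterns (bits), 1..16.
#' @param lh horizontal projector resolution (must be divisible by 2^n).
#' @param lv vertical resolution.
#' @return a \linkS4class{GrayCodePatternSet}.
#' @export
generatePatterns <- function(n, lh = 1024L, lv = 768L) {
  if (n < 1 || n > 16) stop("n must be in 1..16")
  if (lh <= 0 || lv <= 0) stop("resolutions must be > 0")
  if (lh < 2^n) stop("lh must be at least 2^n")
  codes <- floor((seq_len(lh) - 1L) * 2^n / lh)  # per-column stripe code
  patterns <- vector("list", n)
  periods <- numeric(n)
  for (k in seq_len(n)) {
    bit <- bitwAnd(bitwShiftR(as.integer(codes), n - k), 1L)
    patterns[[k]] <- matrix(rep(bit, each = lv), nrow = lv)
    periods[k] <- lh / 2^(k - 1)
  }
  new("GrayCodePatternSet", n = as.integer(n), patterns = patterns,
      lineCount = 2^n - 1, pointBudget = as.numeric(lh) * lv,
      stripePeriods = periods)
}

#' Decode a stack of captured pattern images into per-pixel codes
#'
#' Each pixel is binarized against the midpoint of its own min/max across
#' the stack (robust to albedo); bright = 1, dark = 0, assembled MSB-first
#' in projection order. Pixels whose min/max contrast falls below
#' \code{contrastFloor} are masked invalid.
#'
#' @param intensityStack list of n numeric matrices (equal shape).
#' @param contrastFloor minimum (max - min) intensity for a valid pixel.
#' @return a \linkS4class{CodeMap}.
#' @export
encodePixels <- function(intensityStack, contrastFloor = 0.1) {
  n <- length(intensityStack)
  dims <- dim(intensityStack[[1]])
  if (!all(vapply(intensityStack, function(m) identical(dim(m), dims),
                  logical(1))))
    stop("shape error: pattern images have ragged shapes")
  lo <- Reduce(pmin, intensityStack)
  hi <- Reduce(pmax, intensityStack)
  thr <- (lo + hi) / 2
  # pixels without temporal contrast (always-bright / always-dark) fall back
  # to the global stack midpoint so their code is still well defined
  gthr <- (min(lo) + max(hi)) / 2
  flat <- (hi - lo) < 1e-12
  thr[flat] <- gthr
  codes <- matrix(0L, dims[1], dims[2])
  for (k in seq_len(n))
    codes <- codes * 2L + (intensityStack[[k]] > thr)
  valid <- (hi - lo) >= contrastFloor
  codes[!valid] <- 0L
  new("CodeMap", codes = codes, valid = valid, n = as.integer(n))
}

#' Triangulate a code map against the rig geometry
#'
#' For every valid pixel, intersects the camera ray with the projector light
#' plane of its code: with plane \code{n . x = d} and ray \code{o + t u},
#' \code{t = (d - n . o) / (n . u)}. Rays nearly parallel to their plane and
#' points outside the working volume are masked and counted in the
#' diagnostics.
#'
#' @param codeMap a \linkS4class{CodeMap}.
#' @param rig a \linkS4class{ProjectorCameraRig}.
#' @param parallelTol minimum |n . u| treated as a usable intersection.
#' @return a \linkS4class{PointCloud}; \code{metadata$diagnostics} reports
#'   the masked-pixel counts.
#' @export
triangulatePoints <- function(codeMap, rig, parallelTol = 1e-9) {
  sel <- which(codeMap@valid)
  codes <- codeMap@codes[sel] + 1L  # 1-based plane lookup
  if (max(codes) > nrow(rig@planeNormals))
    stop("every valid code needs a plane equation")
  o <- rig@rayOrigins[sel, , drop = FALSE]
  u <- rig@rayDirs[sel, , drop = FALSE]
  nrm <- rig@planeNormals[codes, , drop = FALSE]
  d <- rig@planeOffsets[codes]
  ndotu <- rowSums(nrm * u)
  parallel <- abs(ndotu) < parallelTol
  t_ <- (d - rowSums(nrm * o)) / ifelse(parallel, NA, ndotu)
  P <- o + t_ * u
  wv <- rig@workingVolume
  inVol <- !parallel &
    P[, 1] >= wv[1, 1] & P[, 1] <= wv[2, 1] &
    P[, 2] >= wv[1, 2] & P[, 2] <= wv[2, 2] &
    P[, 3] >= wv[1, 3] & P[, 3] <= wv[2, 3]
  pointCloud(P[inVol, , drop = FALSE],
             metadata = list(pixelIndex = sel[inVol],
                             diagnostics = list(
                               nValid = length(sel),
                               nParallel = sum(parallel),
                               nOutsideVolume = sum(!inVol & !parallel))))
}

#' Simulated rig: orthographic camera, tilted projector light planes
#'
#' Camera rays travel along +z from a regular (x, y) grid; the projector
#' projects from an angle \code{projectorTilt} about the y axis, so the
#' light plane of code c has unit normal (cos A, 0, sin A) and passes
#' through the center of stripe c on the reference plane z = standoff.
#' Pixel columns are aligned with the stripe centers on that plane, so a
#' flat-reflector round trip is exact.
#'
#' @param n code bits.
#' @param imageDim c(rows, cols) camera resolution.
#' @param width,height lateral working-field size, mm.
#' @param depth working-volume depth, mm (centered on \code{standoff}).
#' @param standoff working distance along z, mm.
#' @param projectorTilt projector obliquity, degrees (0 would make rays and
#'   planes parallel and untriangulable).
#' @export
makeSimulatedRig <- function(n, imageDim = c(64L, 64L), width = 100,
                             height = 80, depth = 80, standoff = 300,
                             projectorTilt = 30) {
  rows <- imageDim[1]; cols <- imageDim[2]
  nStripes <- 2^n
  # pixel (r, c) sits over the center of stripe floor(c * nStripes / cols)
  xs <- (floor((seq_len(cols) - 1L) * nStripes / cols) + 0.5) / nStripes * width
  ys <- seq(0, height, length.out = rows)
  org <- cbind(rep(xs, each = rows), rep(ys, times = cols), 0)
  dirs <- matrix(rep(c(0, 0, 1), each = nrow(org)), ncol = 3L)
  A <- projectorTilt * pi / 180
  centers <- (seq_len(nStripes) - 0.5) / nStripes * width
  new("ProjectorCameraRig", rayOrigins = org, rayDirs = dirs,
      imageDim = as.integer(imageDim),
      planeNormals = matrix(rep(c(cos(A), 0, sin(A)), each = nStripes),
                            ncol = 3L),
      planeOffsets = cos(A) * centers + sin(A) * standoff,
      workingVolume = rbind(c(-1, -1, standoff - depth / 2),
                            c(width + 1, height + 1, standoff + depth / 2)))
}

#' Forward-render a pattern stack of an analytic height surface
#'
#' The surface is \code{z = heightFun(x, y)} (mm) under the simulated rig;
#' each camera pixel observes the stripe whose light plane is nearest its
#' surface point (stripe slabs are equidistant in the plane-normal
#' coordinate).
#'
#' @param patterns a \linkS4class{GrayCodePatternSet}.
#' @param rig rig from \code{\link{makeSimulatedRig}}.
#' @param heightFun vectorized function(x, y) -> z, mm.
#' @return list: \code{stack} (list of images), \code{truePoints} (N x 3),
#'   \code{codes} (true per-pixel codes).
#' @export
renderPatternStack <- function(patterns, rig, heightFun) {
  rows <- rig@imageDim[1]; cols <- rig@imageDim[2]
  x <- rig@rayOrigins[, 1]; y <- rig@rayOrigins[, 2]
  z <- heightFun(x, y)
  nStripes <- nrow(rig@planeNormals)
  v <- cbind(x, y, z) %*% rig@planeNormals[1, ]
  dv <- diff(rig@planeOffsets[1:2])
  code <- pmin(nStripes - 1, pmax(0, round((v - rig@planeOffsets[1]) / dv)))
  stack <- vector("list", patterns@n)
  for (k in seq_len(patterns@n)) {
    bit <- bitwAnd(bitwShiftR(as.integer(code), patterns@n - k), 1L)
    stack[[k]] <- matrix(as.numeric(bit), rows, cols)
  }
  list(stack = stack, truePoints = cbind(x, y, z), codes = as.integer(code))
}

#' Compose turntable views into the common frame
#'
#' Each view cloud is mapped by the exact rotation about the calibrated
#' turntable axes: \code{p_common = A Rz(rot) Ry(tilt) A^-1 p_view} where A
#' is the axis calibration transform.
#'
#' @param views list of \linkS4class{PointCloud}s (view frames).
#' @param angles matrix/list of (rotation, tilt) degree pairs, one per view.
#' @param axisCalibration a \linkS4class{RigidTransform} (identity = axes
#'   coincide with the world frame).
#' @return a single \linkS4class{PointCloud} with per-view provenance in
#'   \code{metadata$viewIndex}.
#' @export
composeTurntableViews <- function(views, angles,
                                  axisCalibration = rigidTransform()) {
  if (is.list(angles)) angles <- do.call(rbind, angles)
  angles <- matrix(angles, ncol = 2L)
  if (nrow(angles) != length(views))
    stop("need one (rotation, tilt) angle pair per view")
  out <- vector("list", length(views))
  for (v in seq_along(views)) {
    Rv <- rotationMatrix("z", angles[v, 1]) %*%
      rotationMatrix("y", angles[v, 2])
    tf <- composeTransforms(axisCalibration,
                            composeTransforms(rigidTransform(Rv),
                                              invertTransform(axisCalibration)))
    out[[v]] <- applyTransform(tf, views[[v]])
  }
  P <- do.call(rbind, lapply(out, positions))
  nrm <- if (all(vapply(out, function(c_) !is.null(c_@normals), logical(1))))
    do.call(rbind, lapply(out, normals)) else NULL
  labs <- if (all(vapply(out, function(c_) !is.null(c_@labels), logical(1))))
    unlist(lapply(out, pointLabels)) else NULL
  pointCloud(P, normals = nrm, labels = labs,
             metadata = list(viewIndex = rep(seq_along(views),
                                             vapply(out, function(c_)
                                               nrow(c_@positions), integer(1)))))
}
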