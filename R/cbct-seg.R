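# CBCT-side computation: iso-surface thresholding, crown-to-volume alignment
# with threshold optimization, and slice-by-slice distance-regularized
# level-set (DRLSE) segmentation guided by the optically scanned crowns.

#' Extract an iso-gray surface from a volume
#'
#' Marching-tetrahedra surface at iso value \code{tau} in world mm.
#' A threshold outside the intensity range yields an empty mesh (flagged via
#' attribute \code{empty}), not an error.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param tau iso threshold, HU.
#' @param smoothSigma optional 3D Gaussian pre-smoothing (voxels, 0 = off);
#'   suppresses noise speckle surfaces without moving a symmetric tissue
#'   boundary.
#' @export
extractIsoSurface <- function(volume, tau, smoothSigma = 0) {
  a <- volume@intensities
  if (smoothSigma > 0) a <- .gaussianSmooth3(a, smoothSigma)
  rng <- range(a)
  if (tau <= rng[1] || tau >= rng[2]) {
    m <- triangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3))
    attr(m, "empty") <- TRUE
    return(m)
  }
  isoSurfaceFromArray(a, tau, volume@spacing, volume@origin)
}

# Separable 3D Gaussian smoothing (replicated edges).
.gaussianSmooth3 <- function(a, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  smooth1 <- function(m, dim_) {
    d <- dim(m)
    idx <- c(rep(1L, r), seq_len(d[dim_]), rep(d[dim_], r))
    m2 <- switch(dim_, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
                 m[, , idx, drop = FALSE])
    out <- array(0, d)
    for (j in seq_along(k)) {
      sl <- switch(dim_,
                   m2[j:(j + d[1] - 1L), , , drop = FALSE],
                   m2[, j:(j + d[2] - 1L), , drop = FALSE],
                   m2[, , j:(j + d[3] - 1L), drop = FALSE])
      out <- out + k[j] * sl
    }
    out
  }
  smooth1(smooth1(smooth1(a, 1L), 2L), 3L)
}

#' Align an optically scanned crown model to a thresholded CBCT volume
#'
#' Landmark (Procrustes) alignment from >= 3 point pairs, refined by ICP
#' restricted to mating pairs within \code{deltaEps}; the discrepancy is the
#' absolute point-to-surface distance from crown vertices to the
#' iso-surface, over mating pairs only.
#'
#' @param crownMesh crown \linkS4class{TriangleMesh} (optical frame).
#' @param volume a \linkS4class{VoxelVolume}.
#' @param tau iso threshold, HU.
#' @param landmarks list with \code{source} and \code{target} (K x 3, K >= 3):
#'   common points picked on the crown and in the volume.
#' @param deltaEps mating-distance bound, mm (default 1).
#' @param smoothSigma Gaussian pre-smoothing for the iso-surface (voxels).
#' @return list: \code{transform}, \code{meanDiscrepancy}, \code{sdDiscrepancy}
#'   (mm), \code{nMating}, \code{isoMesh}.
#' @export
alignCrownsToVolume <- function(crownMesh, volume, tau, landmarks,
                                deltaEps = 1.0, smoothSigma = 0) {
  if (is.null(landmarks$source) || nrow(landmarks$source) < 3L)
    stop("input error: need >= 3 landmark pairs")
  iso <- extractIsoSurface(volume, tau, smoothSigma = smoothSigma)
  if (!nrow(iso@vertices)) stop("alignment error: empty iso-surface")
  tf <- fitRigidTransform(landmarks$source, landmarks$target)
  tv <- iso@vertices
  if (nrow(tv) > 6000L)  # rigid refinement does not need every vertex
    tv <- tv[round(seq(1, nrow(tv), length.out = 6000L)), , drop = FALSE]
  icp <- tryCatch(
    icpRegister(crownMesh@vertices, tv, init = tf,
                maxIter = 15L, tol = 1e-6, rejectDist = deltaEps),
    error = function(e) stop("alignment error: no mating pairs within ",
                             deltaEps, " mm (", conditionMessage(e), ")"))
  moved <- applyTransform(icp$transform, crownMesh@vertices)
  d <- pointToMeshDistance(moved, iso)
  mating <- d <= deltaEps
  if (!any(mating)) stop("alignment error: no mating pairs within deltaEps")
  list(transform = icp$transform, meanDiscrepancy = mean(d[mating]),
       sdDiscrepancy = stats::sd(d[mating]), nMating = sum(mating),
       isoMesh = iso)
}

#' Optimal iso threshold by crown-discrepancy minimization
#'
#' Runs \code{\link{alignCrownsToVolume}} for every threshold in the grid
#' and selects the one minimizing the mean discrepancy between the optical
#' crown and the CBCT iso-surface (ties broken toward the lower threshold).
#'
#' @param crownMesh crown mesh (optical frame).
#' @param volume a \linkS4class{VoxelVolume}.
#' @param tauGrid numeric HU thresholds (>= 2).
#' @param landmarks landmark pairs as in \code{\link{alignCrownsToVolume}}.
#' @param deltaEps mating distance, mm.
#' @param cropPad the volume is cropped to the crown bounding box plus this
#'   margin (mm) before the sweep; only mating surfaces near the crown
#'   matter and the crop keeps speckle iso-surfaces small.
#' @param smoothSigma Gaussian pre-smoothing passed to the iso-surface
#'   extraction (voxels).
#' @return a \linkS4class{ThresholdSweepResult}.
#' @export
optimizeThreshold <- function(crownMesh, volume, tauGrid, landmarks,
                              deltaEps = 1.0, cropPad = 4, smoothSigma = 0.8) {
  if (length(tauGrid) < 2L) stop("need >= 2 thresholds in the grid")
  volume <- .cropVolume(volume, crownMesh@vertices, cropPad)
  means <- sds <- rep(NA_real_, length(tauGrid))
  for (i in seq_along(tauGrid)) {
    res <- tryCatch(alignCrownsToVolume(crownMesh, volume, tauGrid[i],
                                        landmarks, deltaEps,
                                        smoothSigma = smoothSigma),
                    error = function(e) NULL)
    if (!is.null(res)) {
      means[i] <- res$meanDiscrepancy
      sds[i] <- res$sdDiscrepancy
    }
  }
  if (all(is.na(means)))
    stop("sweep error: no threshold produced a usable iso-surface")
  best <- which(means == min(means, na.rm = TRUE))[1L]  # ties -> lower tau
  new("ThresholdSweepResult", thresholds = tauGrid, meanDiscrepancy = means,
      sdDiscrepancy = sds, tauOpt = tauGrid[best])
}

#' Edge indicator g = 1 / (1 + |grad(G_sigma * I)|^2)
#'
#' Gaussian-smooth the slice, take the central-difference gradient magnitude
#' and map through the edge indicator: values near 0 outline object
#' boundaries, values near 1 describe homogeneous regions. Bounds
#' \code{0 < g <= 1} hold for any input; g is exactly 1 wherever the
#' smoothed gradient vanishes (e.g. everywhere on a constant image).
#'
#' @param sliceImage numeric matrix.
#' @param sigma Gaussian SD in pixels.
#' @return matrix of the same shape.
#' @export
edgeIndicator <- function(sliceImage, sigma = 1.5) {
  if (sigma <= 0) stop("sigma must be > 0")
  sm <- .gaussianSmooth(sliceImage, sigma)
  g <- .gradient2(sm)
  1 / (1 + g$gx^2 + g$gy^2)
}

# Separable Gaussian smoothing with replicated edges.
.gaussianSmooth <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(m, r_) {
    m <- rbind(matrix(rep(m[1, ], r_), r_, byrow = TRUE), m,
               matrix(rep(m[nrow(m), ], r_), r_, byrow = TRUE))
    cbind(matrix(rep(m[, 1], r_), ncol = r_), m,
          matrix(rep(m[, ncol(m)], r_), ncol = r_))
  }
  p <- pad(img, r)
  # convolve rows then columns
  out <- apply(p, 2, function(col) stats::filter(col, k, sides = 2))
  out <- t(apply(out, 1, function(row) stats::filter(row, k, sides = 2)))
  out[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img))]
}

# Central-difference gradient with replicated edges.
.gradient2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  gx <- (m[c(2:n1, n1), ] - m[c(1, 1:(n1 - 1)), ]) / 2
  gy <- (m[, c(2:n2, n2)] - m[, c(1, 1:(n2 - 1))]) / 2
  list(gx = gx, gy = gy)
}

#' Default DRLSE parameters
#'
#' @param mu distance-regularization weight.
#' @param lambda edge-length weight.
#' @param alpha signed balloon weight; positive shrinks.
#' @param sigma edge-indicator Gaussian SD, px.
#' @param epsilon Dirac/Heaviside smoothing width, px.
#' @param timeStep explicit time step.
#' @param iterations iterations per propagated slice.
#' @param firstSliceIterations iterations on the initial slice.
#' @param tol convergence: stop when the per-iteration movement of phi in
#'   the narrow band around the zero level falls below this.
#' @export
drlseParams <- function(mu = 0.2, lambda = 5, alpha = 0.5, sigma = 1.5,
                        epsilon = 1.5, timeStep = 1, iterations = 40L,
                        firstSliceIterations = 150L, tol = 5e-4) {
  new("DrlseParams", mu = mu, lambda = lambda, alpha = alpha, sigma = sigma,
      epsilon = epsilon, timeStep = timeStep,
      iterations = as.integer(iterations),
      firstSliceIterations = as.integer(firstSliceIterations), tol = tol)
}

# Smoothed Dirac delta (width epsilon).
.diracEps <- function(x, eps)
  ifelse(abs(x) <= eps, (1 + cos(pi * x / eps)) / (2 * eps), 0)

# d p'(s)/s for the double-well potential: sin(2 pi s)/(2 pi s) for s <= 1,
# (s - 1)/s for s >= 1 (with the removable singularity at 0 set to 1).
.dpFactor <- function(s) {
  out <- ifelse(s <= 1,
                ifelse(s < 1e-10, 1, sin(2 * pi * s) / (2 * pi * s)),
                (s - 1) / pmax(s, 1e-10))
  out
}

# Neumann (mirrored) boundary condition.
.neumann <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c(1, n1), ] <- m[c(3, n1 - 2), ]
  m[, c(1, n2)] <- m[, c(3, n2 - 2)]
  m
}

# Divergence of (fx, fy) by central differences.
.divergence <- function(fx, fy) {
  .gradient2(fx)$gx + .gradient2(fy)$gy
}

# 5-point Laplacian with replicated edges.
.laplacian <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c(2:n1, n1), ] + m[c(1, 1:(n1 - 1)), ] +
    m[, c(2:n2, n2)] + m[, c(1, 1:(n2 - 1))] - 4 * m
}

#' One explicit DRLSE evolution step
#'
#' Gradient flow of the distance-regularized energy: the distance
#' regularization \code{mu div(dp(|grad phi|) grad phi)}, the edge-weighted
#' length term \code{lambda delta(phi) div(g grad phi / |grad phi|)} and the
#' balloon term \code{alpha g delta(phi)} (positive alpha raises phi near
#' the contour, shrinking the negative-inside region).
#'
#' @param phiM numeric matrix phi.
#' @param g edge indicator matrix.
#' @param gGrad list(gx, gy): gradient of g (precomputed).
#' @param params \linkS4class{DrlseParams}.
#' @return updated phi matrix.
#' @export
drlseStep <- function(phiM, g, gGrad, params) {
  phiM <- .neumann(phiM)
  gr <- .gradient2(phiM)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  eps0 <- 1e-10
  nx <- gr$gx / (mag + eps0)
  ny <- gr$gy / (mag + eps0)
  # distance regularization (double-well), computed as
  # div((dp - 1) grad phi) + laplacian(phi) for a stable stencil
  dp <- .dpFactor(mag)
  reg <- .divergence((dp - 1) * gr$gx, (dp - 1) * gr$gy) + .laplacian(phiM)
  # edge term
  dirac <- .diracEps(phiM, params@epsilon)
  edge <- dirac * (gGrad$gx * nx + gGrad$gy * ny + g * .divergence(nx, ny))
  # balloon/area term
  area <- params@alpha * g * dirac
  phiM + params@timeStep *
    (params@mu * reg + params@lambda * edge + area)
}

#' Evolve a level-set field to convergence under DRLSE
#'
#' Explicit-time-step evolution; stops when the zero-level set (the set of
#' negative pixels) stops changing between checks, or at the iteration cap.
#' The CFL-like stability bound \code{timeStep * mu < 0.25} is enforced
#' before evolving.
#'
#' @param phiInit a \linkS4class{LevelSetField} (binary step or a previous
#'   slice's phi).
#' @param g edge indicator matrix (same shape).
#' @param params \linkS4class{DrlseParams}.
#' @param iterations iteration cap (default \code{params@iterations}).
#' @return an evolved \linkS4class{LevelSetField}; extracted zero-level
#'   contours are in \code{attr(, "contours")} (pixel coordinates).
#' @export
drlseEvolve <- function(phiInit, g, params = drlseParams(),
                        iterations = NULL) {
  if (params@timeStep * params@mu >= 0.25)
    stop("parameter error: timeStep * mu must be < 0.25 for stability")
  if (is.null(iterations)) iterations <- params@iterations
  phiM <- phiInit@phi
  if (!all(dim(phiM) == dim(g))) stop("phi and g shapes differ")
  gGrad <- .gradient2(g)
  lastPhi <- phiM
  it <- 0L
  while (it < iterations) {
    steps <- min(10L, iterations - it)
    for (k in seq_len(steps)) {
      phiM <- drlseStep(phiM, g, gGrad, params)
      it <- it + 1L
    }
    band <- abs(phiM) < 2
    move <- if (any(band)) max(abs(phiM[band] - lastPhi[band])) / steps else 0
    if (move < params@tol) break
    lastPhi <- phiM
  }
  out <- new("LevelSetField", phi = phiM, spacing = phiInit@spacing,
             iterations = phiInit@iterations + it)
  attr(out, "contours") <- .zeroContours(phiM)
  out
}

# Closed zero-level contours of phi, in pixel coordinates (rows = x).
# phi is padded with a positive ring so regions clipped by the image border
# still yield closed loops (traced along the border).
.zeroContours <- function(phiM) {
  n1 <- nrow(phiM); n2 <- ncol(phiM)
  pad <- max(abs(phiM)) + 1
  phiP <- matrix(pad, n1 + 2L, n2 + 2L)
  phiP[2:(n1 + 1L), 2:(n2 + 1L)] <- phiM
  cl <- grDevices::contourLines(x = 0:(n1 + 1L), y = 0:(n2 + 1L),
                                z = phiP, levels = 0)
  lapply(cl, function(c_) cbind(c_$x, c_$y))
}

# Binary-step LSF from an inside mask.
.binaryStepLSF <- function(mask, spacing = c(1, 1), c0 = 2) {
  new("LevelSetField", phi = ifelse(mask, -c0, c0) + 0,
      spacing = spacing, iterations = 0L)
}

#' Crown-guided level-set initialization
#'
#' Scans the slice stack from the crown side toward the roots for the first
#' slice whose plane cuts the aligned optical crown in a closed cross
#' section of sufficient area (R0), dilates R0 with a disk structuring
#' element, and builds the binary step LSF (negative inside the dilated
#' contour).
#'
#' @param crownMeshAligned crown mesh already aligned into the volume frame.
#' @param volume a \linkS4class{VoxelVolume}.
#' @param toothId tooth id carried into the outputs.
#' @param dilationRadius disk radius, px (default 3).
#' @param minArea minimal closed-intersection area, in voxel areas
#'   (default 4).
#' @return list: \code{firstSliceIndex}, \code{r0Mask}, \code{initMask},
#'   \code{phiInit}, \code{direction} (slice step toward the roots).
#' @export
initFromCrown <- function(crownMeshAligned, volume, toothId = "11",
                          dilationRadius = 3L, minArea = 4) {
  d <- dim(volume@intensities)
  occ <- voxelizeMesh(crownMeshAligned, d, volume@spacing, volume@origin)
  if (!any(occ))
    stop(paste("manual initialization required: crown does not intersect",
               "the volume (impacted-tooth path)"))
  counts <- apply(occ, 3, sum)
  # the starting slice is the largest closed intersection with the crown:
  # from there every propagated cross section tapers, which suits the
  # shrink-biased (alpha > 0) evolution; tiny dome-top sections would force
  # the contour to grow against the balloon
  if (max(counts) < minArea)
    stop("manual initialization required: no closed intersection slice")
  first <- which.max(counts)
  direction <- -1L  # toward the roots (decreasing slice index)
  r0 <- occ[, , first]
  # largest connected component only (a slice may clip several cusps)
  labs <- EBImage::bwlabel(r0 * 1)
  if (max(labs) > 1) {
    big <- which.max(tabulate(labs[labs > 0]))
    r0 <- labs == big
  }
  brush <- EBImage::makeBrush(2L * dilationRadius + 1L, shape = "disc")
  dil <- EBImage::dilate(r0 * 1, brush) > 0
  list(firstSliceIndex = first, r0Mask = r0, initMask = dil,
       phiInit = .binaryStepLSF(dil, volume@spacing[1:2]),
       direction = direction, toothId = toothId)
}

# Crop a volume to the bounding box of reference points plus a margin (mm).
.cropVolume <- function(volume, pts, pad) {
  d <- dim(volume@intensities)
  lo <- apply(pts, 2, min) - pad
  hi <- apply(pts, 2, max) + pad
  i1 <- pmax(1L, pmin(d, floor((lo - volume@origin) / volume@spacing) + 1L))
  i2 <- pmax(1L, pmin(d, ceiling((hi - volume@origin) / volume@spacing) + 1L))
  new("VoxelVolume",
      intensities = volume@intensities[i1[1]:i2[1], i1[2]:i2[2],
                                       i1[3]:i2[3], drop = FALSE],
      spacing = volume@spacing,
      origin = volume@origin + (i1 - 1L) * volume@spacing,
      labels = NULL)
}

# Rescale a slice to [0, 255] for the edge indicator (HU-scale gradients
# would put g ~ 0 everywhere).
.rescaleSlice <- function(m, lim, top = 60) {
  m[] <- pmin(top, pmax(0, (m - lim[1]) / (lim[2] - lim[1]) * top))
  m
}

#' Segment one tooth through the slice stack by propagated DRLSE
#'
#' The starting slice is initialized from the aligned optical crown (erupted
#' path: the slice of maximal closed intersection, see
#' \code{\link{initFromCrown}}) or from a manual contour (impacted path) and
#' evolved with the first-slice iteration budget; propagation then sweeps
#' from the starting slice toward the root apex and, in a second pass,
#' toward the crown tip, so every step faces a tapering cross section. Each
#' successive slice is initialized from the previous slice's converged
#' region, re-dilated by \code{interSliceDilation} pixels so the contour
#' starts just outside the new cross section. Propagation stops when the
#' segmented area falls below \code{stopArea} voxel areas.
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param crownMeshAligned aligned crown mesh (or NULL for the manual path).
#' @param params \linkS4class{DrlseParams}.
#' @param manualInit optional list(contour = K x 2 world mm polygon,
#'   startSlice = integer, direction = -1 or 1) for impacted teeth.
#' @param toothId tooth id.
#' @param dilationRadius first-slice dilation radius, px.
#' @param interSliceDilation re-dilation between slices, px.
#' @param stopArea propagation stop floor, voxel areas.
#' @param maxAreaGrowth divergence guard: error if the area grows by more
#'   than this factor between adjacent slices.
#' @param rescaleTop slices are rescaled to [0, rescaleTop] before the edge
#'   indicator; the scale controls how saturated g's valley is at strong
#'   edges (gradient magnitudes near 1 give the sharpest localization).
#' @param sliceRange optional c(lo, hi) slice indices clamping the
#'   propagation (the operator's slice-range selection).
#' @return a \linkS4class{SliceContourStack}.
#' @export
segmentTooth <- function(volume, crownMeshAligned = NULL,
                         params = drlseParams(lambda = 2,
                                              iterations = 150L),
                         manualInit = NULL,
                         toothId = "11", dilationRadius = 3L,
                         interSliceDilation = 1L, stopArea = 2,
                         maxAreaGrowth = 3, rescaleTop = 90,
                         sliceRange = NULL) {
  d <- dim(volume@intensities)
  sp <- volume@spacing
  lim <- range(volume@intensities)
  if (!is.null(crownMeshAligned)) {
    ini <- initFromCrown(crownMeshAligned, volume, toothId,
                         dilationRadius = dilationRadius)
    startSlice <- ini$firstSliceIndex
    mask <- ini$initMask
    direction <- ini$direction
  } else if (!is.null(manualInit)) {
    startSlice <- as.integer(manualInit$startSlice)
    direction <- as.integer(manualInit$direction %||% -1L)
    xs <- volume@origin[1] + (seq_len(d[1]) - 1) * sp[1]
    ys <- volume@origin[2] + (seq_len(d[2]) - 1) * sp[2]
    mask <- rasterizePolygons(list(manualInit$contour), xs, ys)
    brush <- EBImage::makeBrush(2L * dilationRadius + 1L, shape = "disc")
    mask <- EBImage::dilate(mask * 1, brush) > 0
  } else stop("either a crown mesh or a manual initialization is required")
  voxArea <- sp[1] * sp[2]
  if (is.null(sliceRange)) sliceRange <- c(1L, d[3])
  brush2 <- EBImage::makeBrush(2L * max(1L, interSliceDilation) + 1L,
                               shape = "disc")
  roiPad <- 12L
  evolveSlice <- function(mask, iz, its) {
    ij <- which(mask, arr.ind = TRUE)
    r1 <- max(1L, min(ij[, 1]) - roiPad); r2 <- min(d[1], max(ij[, 1]) + roiPad)
    c1 <- max(1L, min(ij[, 2]) - roiPad); c2 <- min(d[2], max(ij[, 2]) + roiPad)
    img <- .rescaleSlice(volume@intensities[r1:r2, c1:c2, iz], lim, rescaleTop)
    g <- edgeIndicator(img, params@sigma)
    phi0 <- .binaryStepLSF(mask[r1:r2, c1:c2, drop = FALSE], sp[1:2])
    lsf <- drlseEvolve(phi0, g, params, iterations = its)
    newMask <- matrix(FALSE, d[1], d[2])
    newMask[r1:r2, c1:c2] <- lsf@phi < 0
    world <- lapply(attr(lsf, "contours"), function(l)
      cbind(volume@origin[1] + (r1 - 1 + l[, 1] - 1) * sp[1],
            volume@origin[2] + (c1 - 1 + l[, 2] - 1) * sp[2]))
    list(mask = newMask, area = sum(newMask) * voxArea, contours = world)
  }
  propagate <- function(mask, fromSlice, direction, prevArea) {
    slices <- integer(0); contours <- list(); areas <- numeric(0)
    iz <- fromSlice
    while (iz >= sliceRange[1] && iz <= sliceRange[2]) {
      res <- evolveSlice(mask, iz, params@iterations)
      if (res$area < stopArea * voxArea) break
      if (is.finite(prevArea) && prevArea > 0 &&
          res$area > maxAreaGrowth * prevArea)
        stop(sprintf(
          "propagation error: area diverged at slice %d (%.1f -> %.1f mm^2)",
          iz, prevArea, res$area))
      slices <- c(slices, iz)
      contours <- c(contours, list(res$contours))
      areas <- c(areas, res$area)
      prevArea <- res$area
      mask <- EBImage::dilate(res$mask * 1, brush2) > 0
      iz <- iz + direction
    }
    list(slices = slices, contours = contours, areas = areas)
  }
  # starting slice with the first-slice budget
  start <- evolveSlice(mask, startSlice, params@firstSliceIterations)
  if (start$area < stopArea * voxArea)
    stop("propagation error: no slice produced a contour above the stop floor")
  startMaskDil <- EBImage::dilate(start$mask * 1, brush2) > 0
  down <- propagate(startMaskDil, startSlice + direction, direction,
                    start$area)
  up <- propagate(startMaskDil, startSlice - direction, -direction,
                  start$area)
  ordr <- order(c(up$slices, startSlice, down$slices))
  slices <- c(up$slices, startSlice, down$slices)[ordr]
  contours <- c(up$contours, list(start$contours), down$contours)[ordr]
  areas <- c(up$areas, start$area, down$areas)[ordr]
  new("SliceContourStack", toothId = toothId, sliceIndices = slices,
      contours = contours, areas = areas, spacing = sp,
      origin = volume@origin)
}

#' Reconstruct a closed mesh from a per-slice contour stack
#'
#' Contours are rasterized into a binary volume (even-odd, so holes
#' subtract) and tessellated by marching tetrahedra at 0.5.
#'
#' @param stack a \linkS4class{SliceContourStack}.
#' @param spacing volume spacing override (default: the stack's).
#' @export
contoursToMesh <- function(stack, spacing = NULL) {
  if (length(stack@sliceIndices) < 2L)
    stop("reconstruction error: need contours on >= 2 slices")
  sp <- spacing %||% stack@spacing
  allPts <- do.call(rbind, unlist(stack@contours, recursive = FALSE))
  xr <- range(allPts[, 1]); yr <- range(allPts[, 2])
  xs <- seq(xr[1] - 2 * sp[1], xr[2] + 2 * sp[1], by = sp[1])
  ys <- seq(yr[1] - 2 * sp[2], yr[2] + 2 * sp[2], by = sp[2])
  izr <- range(stack@sliceIndices)
  nz <- izr[2] - izr[1] + 3L
  vol <- array(0, c(length(xs), length(ys), nz))
  for (k in seq_along(stack@sliceIndices)) {
    iz <- stack@sliceIndices[k] - izr[1] + 2L
    vol[, , iz] <- rasterizePolygons(stack@contours[[k]], xs, ys) * 1
  }
  org <- c(xs[1], ys[1], stack@origin[3] + (izr[1] - 2) * sp[3])
  # light smoothing recovers sub-voxel boundary positions from the binary
  # rasterization before tessellation
  vol <- .gaussianSmooth3(vol, 0.5)
  isoSurfaceFromArray(vol, 0.5, spacing = sp, origin = org)
}

#' Segment the alveolar bone envelope and socket it
#'
#' DRLSE propagation from a manually supplied initial contour (the bone has
#' no optical guidance), then per-slice subtraction of every tooth region:
#' the filled bone region minus the filled tooth regions yields the
#' socketed-bone region, recorded as multi-loop contours (holes included).
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param manualInit list(contour, startSlice, direction) as in
#'   \code{\link{segmentTooth}}.
#' @param params \linkS4class{DrlseParams}.
#' @param toothStacks list of \linkS4class{SliceContourStack} for the teeth.
#' @param ... passed to \code{\link{segmentTooth}}.
#' @return a \linkS4class{SliceContourStack} with id "bone"; per-slice
#'   masks of the socketed region are in \code{attr(, "masks")}.
#' @export
segmentBone <- function(volume, manualInit, params = drlseParams(),
                        toothStacks = list(), ...) {
  bone <- segmentTooth(volume, crownMeshAligned = NULL, params = params,
                       manualInit = manualInit, toothId = "bone", ...)
  d <- dim(volume@intensities)
  sp <- volume@spacing
  xs <- volume@origin[1] + (seq_len(d[1]) - 1) * sp[1]
  ys <- volume@origin[2] + (seq_len(d[2]) - 1) * sp[2]
  outContours <- bone@contours
  outAreas <- bone@areas
  masks <- vector("list", length(bone@sliceIndices))
  warned <- character(0)
  for (k in seq_along(bone@sliceIndices)) {
    iz <- bone@sliceIndices[k]
    boneMask <- rasterizePolygons(bone@contours[[k]], xs, ys)
    sub <- boneMask
    for (ts in toothStacks) {
      j <- match(iz, ts@sliceIndices)
      if (is.na(j)) next
      tm <- rasterizePolygons(ts@contours[[j]], xs, ys)
      if (any(tm & !boneMask))
        warned <- unique(c(warned, ts@toothId))
      sub <- sub & !tm
    }
    masks[[k]] <- sub
    phiLike <- ifelse(sub, -1, 1)
    loops <- .zeroContours(phiLike)
    outContours[[k]] <- lapply(loops, function(l)
      cbind(xs[1] + (l[, 1] - 1) * sp[1], ys[1] + (l[, 2] - 1) * sp[2]))
    outAreas[k] <- sum(sub) * sp[1] * sp[2]
  }
  if (length(warned))
    warning("tooth contour outside bone contour on some slice: ",
            paste(warned, collapse = ", "))
  out <- new("SliceContourStack", toothId = "bone",
             sliceIndices = bone@sliceIndices, contours = outContours,
             areas = outAreas, spacing = sp, origin = volume@origin)
  attr(out, "masks") <- masks
  attr(out, "grid") <- list(xs = xs, ys = ys)
  out
}
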