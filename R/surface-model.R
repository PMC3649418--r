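# Optical-surface side of the pipeline: rigid registration and merging of
# the impression and cast scans, mesh reconstruction, covariance-eigenvalue
# surface variation, margin-line splines and crown/gingiva segmentation.

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP with nearest-neighbor correspondences and distance
#' rejection; the update at each iteration is the closed-form SVD (Kabsch)
#' solution, with a reflection corrected by a sign flip of the smallest
#' singular vector. RMS over the retained correspondences is monotone
#' non-increasing across iterations. Optional mutual-nearest filtering
#' (robust against partial overlap, at the cost of a narrower convergence
#' basin) can be enabled with \code{mutual = TRUE}.
#'
#' @param source,target \linkS4class{PointCloud}s or N x 3 matrices
#'   (>= 3 points each).
#' @param init initial \linkS4class{RigidTransform} (identity allowed; a
#'   coarse manual/landmark alignment is the expected input, matching the
#'   workflow this refines).
#' @param maxIter iteration cap.
#' @param tol stop when the RMS improvement falls below this, mm.
#' @param rejectDist correspondences farther than this are discarded, mm.
#' @param mutual keep only mutual-nearest pairs.
#' @return list: \code{transform} (source -> target),
#'   \code{rms} (final, mm), \code{rmsHistory}, \code{iterations}.
#' @export
icpRegister <- function(source, target, init = rigidTransform(),
                        maxIter = 50L, tol = 1e-7, rejectDist = Inf,
                        mutual = FALSE) {
  S <- if (is(source, "PointCloud")) source@positions else as.matrix(source)
  T_ <- if (is(target, "PointCloud")) target@positions else as.matrix(target)
  if (nrow(S) < 3L || nrow(T_) < 3L) stop("both clouds need >= 3 points")
  tf <- init
  rmsHistory <- numeric(0)
  prevRms <- Inf
  best <- list(tf = init, rms = Inf)
  for (it in seq_len(maxIter)) {
    Sm <- applyTransform(tf, S)
    fw <- nearestNeighbors(Sm, T_)
    use <- fw$dist <= rejectDist
    if (mutual) {
      bw <- nearestNeighbors(T_, Sm)
      use <- use & bw$index[fw$index] == seq_len(nrow(Sm))
    }
    if (sum(use) < 3L)
      stop(sprintf(paste0("convergence error: only %d usable correspondences",
                          " (rejectDist = %g mm)"), sum(use), rejectDist))
    rms <- sqrt(mean(fw$dist[use]^2))
    rmsHistory <- c(rmsHistory, rms)
    if (rms < best$rms) best <- list(tf = tf, rms = rms)
    if (prevRms - rms < tol) break
    upd <- fitRigidTransform(Sm[use, , drop = FALSE],
                             T_[fw$index[use], , drop = FALSE])
    tf <- composeTransforms(upd, tf)
    prevRms <- rms
  }
  list(transform = best$tf, rms = best$rms,
       rmsHistory = rmsHistory, iterations = length(rmsHistory))
}

#' Merge impression and cast scans within a tolerance
#'
#' The impression cloud is mapped into the cast frame; points with a
#' counterpart within \code{mergeTolerance} are deduplicated by averaging
#' the matched pair, points without one are kept verbatim. A tolerance of 0
#' degenerates to pure concatenation.
#'
#' @param impression,cast \linkS4class{PointCloud}s.
#' @param transform \linkS4class{RigidTransform} mapping impression into the
#'   cast frame.
#' @param mergeTolerance matching distance, mm (default 0.05).
#' @return merged \linkS4class{PointCloud}.
#' @export
mergeScans <- function(impression, cast, transform = rigidTransform(),
                       mergeTolerance = 0.05) {
  imp <- applyTransform(transform, impression)
  Pi_ <- imp@positions; Pc <- cast@positions
  if (!nrow(Pi_)) return(cast)
  if (!nrow(Pc)) return(imp)
  if (mergeTolerance <= 0) {
    return(pointCloud(rbind(Pi_, Pc),
                      labels = c(impression@labels %||% rep(NA_character_, nrow(Pi_)),
                                 cast@labels %||% rep(NA_character_, nrow(Pc)))))
  }
  nn <- nearestNeighbors(Pi_, Pc)
  matched <- nn$dist <= mergeTolerance
  # each cast point may absorb several impression points; average the group
  usedCast <- unique(nn$index[matched])
  merged <- Pc
  if (any(matched)) {
    grp <- rowsum(Pi_[matched, , drop = FALSE], nn$index[matched])
    cnt <- as.vector(table(nn$index[matched]))
    gi <- as.integer(rownames(grp))
    merged[gi, ] <- (merged[gi, , drop = FALSE] + grp) / (1 + cnt)
  }
  out <- rbind(merged, Pi_[!matched, , drop = FALSE])
  labs <- NULL
  if (!is.null(cast@labels) && !is.null(impression@labels))
    labs <- c(cast@labels, impression@labels[!matched])
  pointCloud(out, labels = labs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Surface variation from covariance eigenanalysis
#'
#' For every point, the covariance of its spherical neighborhood is
#' eigen-decomposed (eigenvalues ascending, \code{l0 <= l1 <= l2}); the
#' surface variation is \code{l0 / (l0 + l1 + l2)}, 0 for a perfectly
#' coplanar neighborhood and 1/3 for a perfectly isotropic one. The
#' eigenvector of the smallest eigenvalue is the local tangent-plane normal;
#' normals are oriented away from \code{insidePoint}. Points with fewer than
#' 3 neighbors are flagged undefined.
#'
#' @param cloud \linkS4class{PointCloud} or N x 3 matrix.
#' @param radius spherical neighborhood radius, mm (default 2).
#' @param insidePoint reference interior point for normal orientation
#'   (default: cloud centroid).
#' @return a \linkS4class{CurvatureField}.
#' @export
surfaceVariation <- function(cloud, radius = 2.0, insidePoint = NULL) {
  if (radius <= 0) stop("radius must be > 0")
  P <- if (is(cloud, "PointCloud")) cloud@positions else as.matrix(cloud)
  n <- nrow(P)
  if (is.null(insidePoint)) insidePoint <- colMeans(P)
  nb <- radiusNeighbors(P, P, radius)
  delta <- rep(NA_real_, n)
  normalsOut <- matrix(NA_real_, n, 3L)
  defined <- rep(FALSE, n)
  for (i in seq_len(n)) {
    idx <- nb[[i]]
    if (length(idx) < 3L) next
    Q <- P[idx, , drop = FALSE]
    Qc <- sweep(Q, 2, colMeans(Q))
    C <- crossprod(Qc)
    ev <- eigen(C, symmetric = TRUE)
    lam <- rev(ev$values)            # ascending l0 <= l1 <= l2
    tot <- sum(lam)
    if (tot <= 0) next
    delta[i] <- max(0, lam[1]) / tot
    v0 <- ev$vectors[, 3L]           # eigenvector of the smallest eigenvalue
    if (sum(v0 * (P[i, ] - insidePoint)) < 0) v0 <- -v0
    normalsOut[i, ] <- v0
    defined[i] <- TRUE
  }
  new("CurvatureField", delta = delta, normals = normalsOut, radius = radius,
      defined = defined)
}

#' Estimate and orient point normals
#'
#' Tangent-plane normals from \code{\link{surfaceVariation}}, oriented away
#' from an interior reference point.
#' @param cloud \linkS4class{PointCloud}.
#' @param radius neighborhood radius, mm.
#' @param insidePoint interior point, default centroid.
#' @export
estimateNormals <- function(cloud, radius = 2.0, insidePoint = NULL) {
  cf <- surfaceVariation(cloud, radius, insidePoint)
  nrm <- cf@normals
  bad <- !cf@defined
  if (any(bad)) nrm[bad, ] <- matrix(rep(c(0, 0, 1), sum(bad)),
                                     ncol = 3L, byrow = TRUE)
  out <- cloud
  out@normals <- nrm / sqrt(rowSums(nrm^2))
  out
}

#' Reconstruct a triangle mesh from an oriented point cloud
#'
#' Classical implicit reconstruction: a signed-distance field (point-to-
#' plane against the nearest oriented sample) is evaluated on a grid at
#' \code{voxelPitch} in a narrow band around the samples, the far field is
#' sign-filled by flood filling from the outside, and the zero level is
#' tessellated by marching tetrahedra.
#'
#' @param cloud \linkS4class{PointCloud}; normals are estimated (and oriented
#'   from the centroid) if absent.
#' @param voxelPitch grid pitch, mm.
#' @param normalRadius radius for normal estimation when needed, mm.
#' @return a \linkS4class{TriangleMesh}.
#' @export
reconstructMesh <- function(cloud, voxelPitch = 0.2, normalRadius = 2.0) {
  P <- cloud@positions
  if (nrow(P) < 100L) stop("reconstruction error: need >= 100 points")
  sv <- svd(sweep(P, 2, colMeans(P)))$d
  if (sv[3] < 1e-9 * sv[1])
    stop("reconstruction error: degenerate (coplanar) cloud")
  if (is.null(cloud@normals)) cloud <- estimateNormals(cloud, normalRadius)
  N <- cloud@normals
  lo <- apply(P, 2, min) - 3 * voxelPitch
  hi <- apply(P, 2, max) + 3 * voxelPitch
  dims <- as.integer(ceiling((hi - lo) / voxelPitch)) + 1L
  xs <- lo[1] + (seq_len(dims[1]) - 1) * voxelPitch
  ys <- lo[2] + (seq_len(dims[2]) - 1) * voxelPitch
  zs <- lo[3] + (seq_len(dims[3]) - 1) * voxelPitch
  # occupancy of sample points -> narrow band by binary dilation
  ijk <- cbind(pmin(dims[1], pmax(1, round((P[, 1] - lo[1]) / voxelPitch) + 1)),
               pmin(dims[2], pmax(1, round((P[, 2] - lo[2]) / voxelPitch) + 1)),
               pmin(dims[3], pmax(1, round((P[, 3] - lo[3]) / voxelPitch) + 1)))
  occ <- array(FALSE, dims)
  occ[ijk] <- TRUE
  band <- occ
  for (rep_ in 1:3) band <- .dilate3(band)
  sel <- which(band)
  i1 <- (sel - 1L) %% dims[1] + 1L
  i2 <- ((sel - 1L) %/% dims[1]) %% dims[2] + 1L
  i3 <- (sel - 1L) %/% (dims[1] * dims[2]) + 1L
  G <- cbind(xs[i1], ys[i2], zs[i3])
  nn <- nearestNeighbors(G, P)
  sdf <- rowSums((G - P[nn$index, , drop = FALSE]) * N[nn$index, , drop = FALSE])
  field <- array(NA_real_, dims)
  field[sel] <- sdf
  # far-field sign by a z-sweep: cells outside the narrow band inherit the
  # sign of the last banded cell below them (the grid floor is outside)
  far <- 4 * voxelPitch
  prev <- matrix(far, dims[1], dims[2])
  for (k in seq_len(dims[3])) {
    slice <- field[, , k]
    known <- !is.na(slice)
    cur <- prev
    cur[known] <- sign(slice[known]) * far
    slice[!known] <- cur[!known]
    field[, , k] <- slice
    prev <- cur
  }
  isoSurfaceFromArray(field, 0, spacing = rep(voxelPitch, 3), origin = lo)
}

# 6-connected binary dilation of a 3D logical array.
.dilate3 <- function(a) {
  d <- dim(a)
  out <- a
  out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
  out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
  out[, , -1] <- out[, , -1] | a[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
  out
}

#' Fit a closed margin-line spline through ordered seed points
#'
#' Closed periodic cubic spline with chord-length parameterization,
#' interpolating every seed.
#'
#' @param seedPoints K x 3 matrix (K >= 4) in loop order, mm.
#' @param toothId ISO 3950 code the margin belongs to.
#' @return a \linkS4class{MarginLine}.
#' @export
fitMarginSpline <- function(seedPoints, toothId = "11") {
  S <- as.matrix(seedPoints)
  if (nrow(S) < 4L) stop("input error: need >= 4 seed points")
  sv <- svd(sweep(S, 2, colMeans(S)))
  if (sv$d[2] < 1e-9 * sv$d[1])
    stop("input error: seed points are collinear")
  # self-intersection test in the best-fit plane
  proj <- sweep(S, 2, colMeans(S)) %*% sv$v[, 1:2]
  if (polygonSelfIntersects(proj))
    stop("input error: seed loop self-intersects")
  closed <- rbind(S, S[1, ])
  chord <- c(0, cumsum(sqrt(rowSums(diff(closed)^2))))
  new("MarginLine", toothId = toothId, seeds = S,
      params = chord[-length(chord)], period = chord[length(chord)])
}

#' Evaluate a margin line
#' @param margin a \linkS4class{MarginLine}.
#' @param t parameter values (chord length, wraps at the period), or
#'   \code{NULL} to evaluate \code{nOut} evenly spaced points.
#' @param nOut number of points when \code{t} is NULL.
#' @return N x 3 matrix, mm.
#' @export
marginPoints <- function(margin, t = NULL, nOut = 200L) {
  if (is.null(t)) t <- seq(0, margin@period, length.out = nOut + 1L)[-(nOut + 1L)]
  tt <- c(margin@params, margin@period)
  S <- rbind(margin@seeds, margin@seeds[1, ])
  sapply(1:3, function(k)
    splinefun(tt, S[, k], method = "periodic")(t %% margin@period))
}

#' Segment tooth crowns from the gingiva on a mouth mesh
#'
#' Each margin loop is projected onto the mesh; vertices enclosed by the
#' loop (region grown across mesh edges from the vertex nearest the loop
#' center, without crossing the loop) are assigned the margin's tooth id and
#' the remainder is gingiva. The projected boundary is relaxed onto the
#' locally maximal surface-variation ridge within \code{snapBand} of the
#' loop: boundary-adjacent vertices inside the band whose delta_n exceeds
#' the ridge level join the crown.
#'
#' @param mesh mouth \linkS4class{TriangleMesh}.
#' @param curvature \linkS4class{CurvatureField} computed on the mesh
#'   vertices.
#' @param margins list of \linkS4class{MarginLine}s, one per tooth.
#' @param snapBand ridge-relaxation band around the projected loop, mm.
#' @return a \linkS4class{SegmentedMouthModel}.
#' @export
segmentCrowns <- function(mesh, curvature, margins, snapBand = 1.0) {
  V <- mesh@vertices
  nv <- nrow(V)
  assignment <- rep("gingiva", nv)
  ed <- meshEdges(mesh)$edges
  adj <- split(c(ed[, 2L], ed[, 1L]), c(ed[, 1L], ed[, 2L]))
  for (m in margins) {
    loop3 <- marginPoints(m, nOut = 150L)
    loop2 <- loop3[, 1:2, drop = FALSE]
    insidePoly <- pointInPolygon(V[, 1:2, drop = FALSE], loop2)
    if (!any(insidePoly))
      stop(sprintf("segmentation error: margin of tooth %s encloses no vertices",
                   m@toothId))
    distToLoop <- nearestNeighbors(V, loop3)$dist
    center <- colMeans(loop3)
    cand <- which(insidePoly)
    seed <- cand[which.max(V[cand, 3] - 0.05 *
                             sqrt((V[cand, 1] - center[1])^2 +
                                    (V[cand, 2] - center[2])^2))]
    # grow from the interior seed across mesh edges; the projected loop acts
    # as a barrier (vertices close to it are blocked, not crossed)
    blocked <- distToLoop <= 0.5
    inRegion <- rep(FALSE, nv)
    inRegion[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nbr <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nbr <- nbr[!inRegion[nbr] & !blocked[nbr]]
      inRegion[nbr] <- TRUE
      frontier <- nbr
    }
    # snap the boundary onto the surface-variation ridge: blocked vertices
    # within the band join the crown when their delta_n reaches the ridge
    # level, so the final boundary follows the locally maximal-curvature path
    ridgeLevel <- stats::quantile(curvature@delta[distToLoop <= snapBand],
                                  0.5, na.rm = TRUE)
    if (is.finite(ridgeLevel)) {
      repeat {
        boundary <- which(inRegion)
        nbr <- unique(unlist(adj[as.character(boundary)], use.names = FALSE))
        grow <- nbr[!inRegion[nbr] & distToLoop[nbr] <= snapBand &
                      !is.na(curvature@delta[nbr]) &
                      curvature@delta[nbr] >= ridgeLevel]
        if (!length(grow)) break
        inRegion[grow] <- TRUE
      }
    }
    assignment[inRegion] <- m@toothId
  }
  new("SegmentedMouthModel", mesh = mesh, assignment = assignment,
      margins = margins)
}

#' Extract one crown sub-mesh from a segmented mouth model
#' @param model a \linkS4class{SegmentedMouthModel}.
#' @param id tooth id.
#' @export
crownSubMesh <- function(model, id) {
  keep <- which(model@assignment == id)
  fsel <- apply(matrix(model@mesh@faces %in% keep, ncol = 3L), 1L, all)
  f <- model@mesh@faces[fsel, , drop = FALSE]
  remap <- match(seq_len(nrow(model@mesh@vertices)), keep)
  triangleMesh(model@mesh@vertices[keep, , drop = FALSE],
               matrix(remap[f], ncol = 3L),
               vertexLabels = rep(id, length(keep)))
}
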