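# Fusion of optical crowns with CBCT roots and assembly of the multi-body
# orthodontic model.

# Ordered boundary loop vertices (3D coords) of an open mesh, largest loop
# first.
.orderedLoops <- function(mesh) {
  loops <- boundaryLoops(mesh)
  loops[order(-vapply(loops, length, integer(1)))]
}

# Parity test: are points inside a closed mesh (ray cast along +z)?
pointsInsideMesh <- function(pts, mesh) {
  v <- mesh@vertices; f <- mesh@faces
  cnt <- integer(nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]; pz <- pts[, 3]
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    if (max(a[1], b[1], c_[1]) < min(px) || min(a[1], b[1], c_[1]) > max(px))
      next
    d <- (b[2] - c_[2]) * (a[1] - c_[1]) + (c_[1] - b[1]) * (a[2] - c_[2])
    if (abs(d) < 1e-14) next
    w1 <- ((b[2] - c_[2]) * (px - c_[1]) + (c_[1] - b[1]) * (py - c_[2])) / d
    w2 <- ((c_[2] - a[2]) * (px - c_[1]) + (a[1] - c_[1]) * (py - c_[2])) / d
    w3 <- 1 - w1 - w2
    ok <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(ok)) next
    z <- w1[ok] * a[3] + w2[ok] * b[3] + w3[ok] * c_[3]
    hit <- which(ok)[z > pz[ok]]
    cnt[hit] <- cnt[hit] + 1L
  }
  cnt %% 2L == 1L
}

#' Fuse an optical crown with a CBCT root mesh
#'
#' The optical crown is kept verbatim; CBCT faces lying within the crown's
#' occupancy (on the crown side of the crown rim plane) are discarded and
#' the remaining root boundary loop is stitched to the crown rim across the
#' seam band by an angular-merge triangulation.
#'
#' @param crownMesh open optical crown mesh (boundary = margin rim).
#' @param rootStackMesh closed CBCT tooth mesh.
#' @param seamBand stitching band, mm (default 0.5).
#' @param toothId ISO 3950 id for the resulting tooth.
#' @return a \linkS4class{ToothModel}; fused faces are tagged
#'   "optical", "cbct" or "seam".
#' @export
fuseCrownRoot <- function(crownMesh, rootStackMesh, seamBand = 0.5,
                          toothId = "11") {
  nnd <- nearestNeighbors(crownMesh@vertices, rootStackMesh@vertices)
  if (min(nnd$dist) > 10 * seamBand + 2)
    stop("fusion error: crown and root do not overlap (misalignment suspected)")
  crownLoops <- .orderedLoops(crownMesh)
  if (!length(crownLoops)) stop("fusion error: crown mesh has no open rim")
  rimIdx <- crownLoops[[1]]
  rim <- crownMesh@vertices[rimIdx, , drop = FALSE]
  rimC <- colMeans(rim)
  nrm <- svd(sweep(rim, 2, rimC))$v[, 3]
  crownC <- colMeans(crownMesh@vertices)
  if (sum((crownC - rimC) * nrm) < 0) nrm <- -nrm  # points toward the crown
  # drop CBCT faces on the crown side of the rim plane (minus the seam band)
  fc <- faceCentroids(rootStackMesh)
  side <- as.vector(sweep(fc, 2, rimC) %*% nrm)
  keepF <- side < 0
  if (all(keepF) || !any(keepF))
    stop("fusion error: rim plane does not cut the CBCT model")
  rootCut <- triangleMesh(rootStackMesh@vertices,
                          rootStackMesh@faces[keepF, , drop = FALSE])
  usedV <- sort(unique(as.vector(rootCut@faces)))
  remap <- match(seq_len(nrow(rootCut@vertices)), usedV)
  rootCut <- triangleMesh(rootCut@vertices[usedV, , drop = FALSE],
                          matrix(remap[rootCut@faces], ncol = 3L))
  rootLoops <- .orderedLoops(rootCut)
  if (!length(rootLoops)) stop("fusion error: cut root has no boundary loop")
  loopC <- vapply(rootLoops, function(l)
    sum((colMeans(rootCut@vertices[l, , drop = FALSE]) - rimC)^2), numeric(1))
  rootLoopIdx <- rootLoops[[which.min(loopC)]]
  # seam: angular merge of the two loops around the rim normal
  basis <- svd(sweep(rim, 2, rimC))$v[, 1:2]
  angOf <- function(pts) {
    uv <- sweep(pts, 2, rimC) %*% basis
    atan2(uv[, 2], uv[, 1])
  }
  aC <- angOf(rim); aR <- angOf(rootCut@vertices[rootLoopIdx, , drop = FALSE])
  oC <- order(aC); oR <- order(aR)
  rimIdx <- rimIdx[oC]; aC <- aC[oC]
  rootLoopIdx <- rootLoopIdx[oR]; aR <- aR[oR]
  nC <- length(rimIdx); nR <- length(rootLoopIdx)
  nvCrown <- nrow(crownMesh@vertices)
  seam <- list()
  i <- 1L; j <- 1L
  repeat {
    nextC <- aC[(i %% nC) + 1L] + if (i == nC) 2 * pi else 0
    nextR <- aR[(j %% nR) + 1L] + if (j == nR) 2 * pi else 0
    if (i > nC && j > nR) break
    advanceCrown <- (nextC <= nextR && i <= nC) || j > nR
    if (advanceCrown && i <= nC) {
      i2 <- (i %% nC) + 1L
      seam[[length(seam) + 1L]] <- c(rimIdx[i], rimIdx[i2],
                                     nvCrown + rootLoopIdx[(j - 1L) %% nR + 1L])
      i <- i + 1L
    } else {
      j2 <- (j %% nR) + 1L
      seam[[length(seam) + 1L]] <- c(rimIdx[(i - 1L) %% nC + 1L],
                                     nvCrown + rootLoopIdx[j2],
                                     nvCrown + rootLoopIdx[(j - 1L) %% nR + 1L])
      j <- j + 1L
    }
  }
  seamF <- do.call(rbind, seam)
  fusedV <- rbind(crownMesh@vertices, rootCut@vertices)
  fusedF <- rbind(crownMesh@faces, rootCut@faces + nvCrown, seamF)
  tags <- c(rep("optical", nrow(crownMesh@faces)),
            rep("cbct", nrow(rootCut@faces)),
            rep("seam", nrow(seamF)))
  fused <- triangleMesh(fusedV, fusedF, faceTags = tags)
  new("ToothModel", toothId = toothId, crownMesh = crownMesh,
      rootMesh = rootStackMesh, fusedMesh = fused, pose = rigidTransform())
}

# Pairwise interpenetration flags among the model bodies.
.collisionReport <- function(model, nSamples = 300L) {
  bodies <- c(lapply(model@teeth, function(t)
    applyTransform(t@pose, t@fusedMesh)),
    if (nrow(model@bone@faces)) list(model@bone))
  names(bodies) <- c(vapply(model@teeth, function(t) t@toothId, character(1)),
                     if (nrow(model@bone@faces)) "bone")
  n <- length(bodies)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    pts <- samplePointsOnMesh(bodies[[i]], nSamples, seed = 11L)@positions
    hit <- any(pointsInsideMesh(pts, bodies[[j]]))
    if (!hit) {
      pts2 <- samplePointsOnMesh(bodies[[j]], nSamples, seed = 11L)@positions
      hit <- any(pointsInsideMesh(pts2, bodies[[i]]))
    }
    rows[[length(rows) + 1L]] <- data.frame(bodyA = names(bodies)[i],
                                            bodyB = names(bodies)[j],
                                            colliding = hit)
  }
  if (!length(rows)) return(data.frame(bodyA = character(0),
                                       bodyB = character(0),
                                       colliding = logical(0)))
  do.call(rbind, rows)
}

#' Assemble the multi-body orthodontic model
#'
#' @param teeth list of \linkS4class{ToothModel}.
#' @param gingiva gingiva \linkS4class{TriangleMesh}.
#' @param boneStack socketed-bone \linkS4class{SliceContourStack} (from
#'   \code{\link{segmentBone}}), or an already meshed \code{TriangleMesh}.
#' @param spacing contour meshing spacing (when boneStack is a stack).
#' @param frame frame tag; all inputs must share it.
#' @param checkCollisions compute the pairwise interpenetration report.
#' @return a \linkS4class{MultiBodyModel}.
#' @export
buildOrthodonticModel <- function(teeth, gingiva, boneStack = NULL,
                                  spacing = NULL, frame = "cbct",
                                  checkCollisions = TRUE) {
  bone <- if (is(boneStack, "TriangleMesh")) boneStack
    else if (is(boneStack, "SliceContourStack")) contoursToMesh(boneStack, spacing)
    else triangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  model <- new("MultiBodyModel", teeth = teeth, gingiva = gingiva,
               bone = bone, frame = frame,
               collisions = data.frame())
  model@collisions <- if (checkCollisions) .collisionReport(model)
    else data.frame()
  model
}

#' Rigidly move one tooth within the model
#'
#' Composes the given transform onto that tooth's pose; every other body is
#' untouched (bit-identical), and the collision report is refreshed.
#'
#' @param model a \linkS4class{MultiBodyModel}.
#' @param toothId_ id of the tooth to move.
#' @param transform a \linkS4class{RigidTransform}.
#' @export
transformTooth <- function(model, toothId_, transform) {
  ids <- vapply(model@teeth, function(t) t@toothId, character(1))
  k <- match(toothId_, ids)
  if (is.na(k)) stop("lookup error: unknown tooth id ", toothId_)
  model@teeth[[k]]@pose <- composeTransforms(transform, model@teeth[[k]]@pose)
  model@collisions <- .collisionReport(model)
  model
}

#' Export a multi-body model as one STL per body plus a JSON manifest
#'
#' @param model a \linkS4class{MultiBodyModel}.
#' @param directory output directory.
#' @return invisibly, the manifest path.
#' @export
exportModel <- function(model, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  bodies <- list()
  for (t in model@teeth) {
    f <- file.path(directory, sprintf("tooth_%s.stl", t@toothId))
    writeSTL(applyTransform(t@pose, t@fusedMesh), f, binary = FALSE)
    bodies[[length(bodies) + 1L]] <- list(
      kind = "tooth", toothId = t@toothId, file = basename(f),
      pose = list(rotation = as.vector(t@pose@rotation),
                  translation = t@pose@translation),
      provenance = as.list(table(t@fusedMesh@faceTags)))
  }
  if (nrow(model@gingiva@faces)) {
    writeSTL(model@gingiva, file.path(directory, "gingiva.stl"),
             binary = FALSE)
    bodies[[length(bodies) + 1L]] <- list(kind = "gingiva",
                                          file = "gingiva.stl")
  }
  if (nrow(model@bone@faces)) {
    writeSTL(model@bone, file.path(directory, "bone.stl"), binary = FALSE)
    bodies[[length(bodies) + 1L]] <- list(kind = "bone", file = "bone.stl")
  }
  manifest <- list(units = "mm", frame = model@frame, bodies = bodies)
  mp <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}

#' Re-import a model exported by \code{\link{exportModel}}
#' @param directory directory holding the manifest and STL files.
#' @export
importModel <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = FALSE)
  teeth <- list(); ging <- bone <- triangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3))
  for (b in manifest$bodies) {
    mesh <- readSTL(file.path(directory, b$file))
    if (b$kind == "tooth") {
      teeth[[length(teeth) + 1L]] <-
        new("ToothModel", toothId = b$toothId, crownMesh = mesh,
            rootMesh = mesh, fusedMesh = mesh, pose = rigidTransform())
    } else if (b$kind == "gingiva") ging <- mesh else bone <- mesh
  }
  new("MultiBodyModel", teeth = teeth, gingiva = ging, bone = bone,
      frame = manifest$frame, collisions = data.frame())
}
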