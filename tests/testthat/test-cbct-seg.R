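test_that("iso-surface extraction is sub-voxel accurate on analytic shapes", {
  # sphere of HU 1500 in 0 background
  n <- 40; sp <- 0.5
  ax <- (seq_len(n) - (n + 1) / 2) * sp
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  vol <- new("VoxelVolume", intensities = ifelse(r2 <= 6^2, 1500, 0),
             spacing = rep(sp, 3), origin = rep(ax[1], 3))
  # light pre-smoothing recovers the sub-voxel boundary of the binary field
  mesh <- extractIsoSurface(vol, 750, smoothSigma = 0.8)
  rads <- sqrt(rowSums(vertices(mesh)^2))
  expect_lt(max(abs(rads - 6)), sp / 2)

  # threshold above the maximum: empty mesh, flagged, no error
  emp <- extractIsoSurface(vol, 2000)
  expect_equal(nrow(vertices(emp)), 0L)
  expect_true(isTRUE(attr(emp, "empty")))

  # nested spheres produce two connected components
  shells <- ifelse(r2 <= 3^2, 0, ifelse(r2 <= 6^2, 1500, 0))
  vol2 <- new("VoxelVolume", intensities = shells, spacing = rep(sp, 3),
              origin = rep(ax[1], 3))
  m2 <- extractIsoSurface(vol2, 750)
  comp <- orthofuse:::vertexComponents(m2)
  expect_equal(length(unique(comp[unique(as.vector(faces(m2)))])), 2L)
})

test_that("crown-to-volume alignment mates within delta_eps and refines", {
  jaw <- oneToothJaw()
  vol <- oneToothVolume(seed = 2)
  crown <- jaw@crownMeshes[[1]]
  idx <- c(1, 40, 90)
  lm <- list(source = vertices(crown)[idx, ], target = vertices(crown)[idx, ])

  res <- alignCrownsToVolume(crown, vol, 900, lm, smoothSigma = 0.8)
  expect_lt(res$meanDiscrepancy, 0.2)  # half of the 0.4 mm voxel

  # perturbed landmarks: ICP refinement must beat the landmark-only stage
  lmOff <- list(source = lm$source,
                target = lm$target + matrix(c(0.4, -0.3, 0.25), 3, 3,
                                            byrow = TRUE))
  tf0 <- fitRigidTransform(lmOff$source, lmOff$target)
  iso <- extractIsoSurface(vol, 900, smoothSigma = 0.8)
  d0 <- orthofuse:::pointToMeshDistance(applyTransform(tf0, vertices(crown)),
                                        iso)
  res2 <- alignCrownsToVolume(crown, vol, 900, lmOff, smoothSigma = 0.8)
  expect_lt(res2$meanDiscrepancy, mean(d0[d0 <= 1]))

  expect_error(alignCrownsToVolume(crown, vol, 900,
                                   list(source = lm$source[1:2, ],
                                        target = lm$target[1:2, ])),
               ">= 3 landmark")
})

test_that("threshold sweep finds an interior optimum near the half-intensity", {
  jaw <- oneToothJaw()
  vol <- oneToothVolume(seed = 2)
  crown <- jaw@crownMeshes[[1]]
  idx <- c(1, 40, 90)
  lm <- list(source = vertices(crown)[idx, ], target = vertices(crown)[idx, ])
  grid <- seq(500, 1300, by = 100)
  sw <- optimizeThreshold(crown, vol, grid, lm)
  # interior minimum, and tau_opt attains it by definition
  k <- match(tauOpt(sw), sw@thresholds)
  expect_gt(k, 1); expect_lt(k, length(grid))
  expect_true(all(sw@meanDiscrepancy[k] <=
                    sw@meanDiscrepancy[is.finite(sw@meanDiscrepancy)]))
  # tooth/soft half-intensity boundary: (1500 + 300) / 2 = 900
  expect_lte(abs(tauOpt(sw) - 900), 100)

  expect_error(optimizeThreshold(crown, vol, 900, lm), ">= 2")
  flat <- new("VoxelVolume", intensities = array(100, c(8, 8, 8)),
              spacing = rep(1, 3), origin = rep(0, 3))
  expect_error(optimizeThreshold(jaw@crownMeshes[[1]], flat,
                                 c(50, 150), lm), "sweep error")
})

test_that("edge indicator localizes steps and respects its bounds", {
  img <- matrix(0, 40, 40); img[21:40, ] <- 100
  g <- edgeIndicator(img, 1.5)
  # brute-force scan for the minimum along each row
  amin <- apply(g, 2, which.min)
  expect_true(all(abs(amin - 20.5) <= 1))
  expect_true(min(g) > 0 && max(g) <= 1)
  set.seed(9)
  gn <- edgeIndicator(matrix(rnorm(400), 20), 1.5)
  expect_true(min(gn) > 0 && max(gn) <= 1)
  expect_error(edgeIndicator(img, 0), "sigma")
})

test_that("DRLSE keeps a distance-regularized profile and obeys alpha signs", {
  g <- edgeIndicator(diskImage(), 1.5)
  # shrink from an enclosing square
  mask <- matrix(FALSE, 64, 64); mask[8:56, 8:56] <- TRUE
  lsf <- drlseEvolve(binaryStepField(mask), g, drlseParams(alpha = 0.5),
                     iterations = 2500)
  pts <- do.call(rbind, attr(lsf, "contours"))
  rr <- sqrt((pts[, 1] - 32)^2 + (pts[, 2] - 32)^2)
  expect_lt(max(abs(rr - 15)), 1.5)  # converged near the disk boundary

  # signed-distance band: |grad phi| ~ 1 near the zero level
  gr <- orthofuse:::.gradient2(phi(lsf))
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  band <- abs(phi(lsf)) < 1
  expect_gte(mean(mag[band] >= 0.8 & mag[band] <= 1.2), 0.9)

  # expand from inside with negative alpha
  rr0 <- outer(1:64, 1:64, function(x, y) sqrt((x - 32)^2 + (y - 32)^2))
  lsf2 <- drlseEvolve(binaryStepField(rr0 <= 12), g,
                      drlseParams(alpha = -0.5, tol = 1e-4),
                      iterations = 3000)
  pts2 <- do.call(rbind, attr(lsf2, "contours"))
  rr2 <- sqrt((pts2[, 1] - 32)^2 + (pts2[, 2] - 32)^2)
  expect_gt(mean(rr2), 13.5)  # expanded from 12 toward 15
  expect_lt(max(abs(rr2 - 15)), 1.5)

  # stability guard
  expect_error(drlseEvolve(binaryStepField(mask), g,
                           drlseParams(mu = 0.3, timeStep = 1)),
               "stability")

  # alpha = 0 on a blank image: curvature flow, contour length non-increasing
  gFlat <- edgeIndicator(matrix(0, 64, 64), 1.5)
  phiC <- binaryStepField(rr0 <= 18)
  lens <- c()
  for (k in 1:4) {
    phiC <- drlseEvolve(phiC, gFlat, drlseParams(alpha = 0, tol = 0),
                        iterations = 15)
    loops <- attr(phiC, "contours")
    if (!length(loops)) break
    ct <- do.call(rbind, lapply(loops, function(l) rbind(l, l[1, ])))
    lens <- c(lens, sum(sqrt(rowSums(diff(ct)^2))))
  }
  expect_gte(length(lens), 3L)
  expect_true(all(diff(lens) <= 1e-6))
})

test_that("crown-guided initialization picks the maximal closed section", {
  jaw <- oneToothJaw()
  vol <- oneToothVolume(seed = 2)
  crown <- jaw@crownMeshes[[1]]
  ini <- initFromCrown(crown, vol, "11")

  # documented semantics: the starting slice maximizes the crown section
  zs <- origin(vol)[3] + (seq_len(dim(intensities(vol))[3]) - 1) * 0.4
  areas <- jaw@analytic$crossSectionArea(1, zs)
  crownZ <- zs >= jaw@specs[[1]]@pose@translation[3]
  best <- which(crownZ)[which.max(areas[crownZ])]
  expect_lte(abs(ini$firstSliceIndex - best), 1L)

  # C_init strictly contains R0 with at least 1 px margin
  expect_true(all(ini$initMask[ini$r0Mask]))
  grown <- EBImage::dilate(ini$r0Mask * 1, EBImage::makeBrush(3, "disc")) > 0
  expect_true(all(ini$initMask[grown]))

  # the binary step LSF is negative inside and positive outside
  expect_true(all(phi(ini$phiInit)[ini$initMask] < 0))
  expect_true(all(phi(ini$phiInit)[!ini$initMask] > 0))

  # a crown fully outside the volume requests manual initialization
  offCrown <- applyTransform(rigidTransform(diag(3), c(500, 0, 0)), crown)
  expect_error(initFromCrown(offCrown, vol, "11"), "manual")
})

test_that("propagated DRLSE recovers the tooth and supports the manual path", {
  jaw <- oneToothJaw()
  vol <- oneToothVolume(seed = 2)
  st <- segmentTooth(vol, jaw@crownMeshes[[1]], toothId = "11")
  expect_equal(toothId(st), "11")

  segVol <- sum(st@areas) * spacing(vol)[3]
  trueVol <- jaw@analytic$toothVolume(1)
  expect_lt(abs(segVol - trueVol) / trueVol, 0.05)
  ds <- contourOracleDistances(jaw, 1, st, vol)
  expect_lte(mean(ds, na.rm = TRUE), spacing(vol)[1])

  # impacted-tooth path: manual contour at the widest slice, no crown mesh
  zW <- 2.2
  izW <- round((zW - origin(vol)[3]) / spacing(vol)[3]) + 1L
  zSlice <- origin(vol)[3] + (izW - 1) * spacing(vol)[3]
  s <- jaw@specs[[1]]
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  sc <- orthofuse:::.crownScale((zSlice - s@pose@translation[3]) / s@crownHeight)
  rb <- sc * ((abs(cos(th)) / s@crownRadii[1])^4 +
                (abs(sin(th)) / s@crownRadii[2])^4)^(-1 / 4)
  poly <- cbind(rb * cos(th) + s@pose@translation[1],
                rb * sin(th) + s@pose@translation[2])
  stM <- segmentTooth(vol, crownMeshAligned = NULL,
                      manualInit = list(contour = poly, startSlice = izW),
                      toothId = "13")
  segVolM <- sum(stM@areas) * spacing(vol)[3]
  expect_lt(abs(segVolM - trueVol) / trueVol, 0.08)

  expect_error(segmentTooth(vol), "crown mesh or a manual")
})

test_that("contour stacks mesh into closed surfaces at sub-voxel accuracy", {
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  circ <- cbind(5 * cos(th), 5 * sin(th))
  stk <- new("SliceContourStack", toothId = "11", sliceIndices = 1:20,
             contours = rep(list(list(circ)), 20), areas = rep(pi * 25, 20),
             spacing = c(0.4, 0.4, 0.4), origin = c(0, 0, 0))
  cyl <- contoursToMesh(stk)
  v <- vertices(cyl)
  mid <- abs(v[, 3] - mean(range(v[, 3]))) < 2
  expect_lte(max(abs(sqrt(v[mid, 1]^2 + v[mid, 2]^2) - 5)), 0.2 + 1e-9)
  # closed mesh: no boundary edges
  expect_equal(sum(orthofuse:::meshEdges(cyl)$count == 1L), 0L)

  one <- new("SliceContourStack", toothId = "11", sliceIndices = 1L,
             contours = list(list(circ)), areas = pi * 25,
             spacing = c(0.4, 0.4, 0.4), origin = c(0, 0, 0))
  expect_error(contoursToMesh(one), ">= 2 slices")
})

test_that("bone segmentation sockets the teeth by per-slice subtraction", {
  jaw <- twoToothJaw()
  vol <- twoToothVolume()
  st1 <- twoToothStack1()
  bn <- boneStackFixture()
  expect_equal(toothId(bn), "bone")

  masks <- attr(bn, "masks"); grid <- attr(bn, "grid")
  common <- intersect(sliceIndices(bn), sliceIndices(st1))
  expect_gt(length(common), 3L)
  for (iz in common[1:3]) {
    kB <- match(iz, sliceIndices(bn)); kT <- match(iz, sliceIndices(st1))
    tm <- orthofuse:::rasterizePolygons(sliceContours(st1)[[kT]],
                                        grid$xs, grid$ys)
    # socketed bone is pixelwise disjoint from the tooth
    expect_equal(sum(tm & masks[[kB]]), 0L)
    # additivity where the tooth is nested in the bone
    boneMask <- orthofuse:::rasterizePolygons(sliceContours(bn)[[kB]],
                                              grid$xs, grid$ys)
    expect_equal(sum(masks[[kB]]), sum(boneMask | masks[[kB]]) -
                   sum(tm & (boneMask | masks[[kB]])))
  }

  # envelope recovery on a mid-root slice: the segmented bone boundary lies
  # within one voxel (mean) of the analytic boundary, and the masks agree
  iz <- common[2]
  zw <- origin(vol)[3] + (iz - 1) * spacing(vol)[3]
  kB <- match(iz, sliceIndices(bn))
  gxy <- expand.grid(x = grid$xs, y = grid$ys)
  world <- cbind(gxy$x, gxy$y, zw)
  trueBone <- matrix(labelPoints(jaw, world) == 2L, length(grid$xs))
  got <- masks[[kB]]
  expect_gt(mean(got == trueBone), 0.95)
  boundaryOf <- function(m) {
    d <- dim(m)
    inner <- m[c(2:d[1], d[1]), ] & m[c(1, 1:(d[1] - 1)), ] &
      m[, c(2:d[2], d[2])] & m[, c(1, 1:(d[2] - 1))]
    which(m & !inner, arr.ind = TRUE)
  }
  bG <- boundaryOf(got); bT <- boundaryOf(trueBone)
  bGmm <- cbind(grid$xs[bG[, 1]], grid$ys[bG[, 2]], 0)
  bTmm <- cbind(grid$xs[bT[, 1]], grid$ys[bT[, 2]], 0)
  expect_lte(mean(nearestNeighbors(bGmm, bTmm)$dist), spacing(vol)[1])
})
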