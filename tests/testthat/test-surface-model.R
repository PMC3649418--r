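test_that("ICP refines coarse alignments and reports its failure modes", {
  jaw <- twoToothJaw()
  cl <- positions(samplePointsOnMesh(mouthSurfaceMesh(jaw), 2500, seed = 4))

  # identical clouds from identity: identity transform, rms ~ 0
  res0 <- icpRegister(cl, cl)
  expect_lt(res0$rms, 1e-9)
  expect_lt(rotationAngle(res0$transform@rotation), 1e-6)

  # known transform, coarse (centroid) init, exact recovery
  ctr <- colMeans(cl)
  tf <- rigidTransform(rotationMatrix("z", 10), c(2, 1, 0))
  src <- sweep(applyTransform(invertTransform(tf), sweep(cl, 2, ctr)), 2,
               ctr, "+")
  init <- rigidTransform(diag(3), colMeans(cl) - colMeans(src))
  res <- icpRegister(src, cl, init = init, maxIter = 80, tol = 1e-12)
  expect_lt(res$rms, 1e-3)
  expect_lt(rotationAngle(t(res$transform@rotation) %*% tf@rotation), 1e-3)

  # applying the recovered transform reduces RMS relative to the init
  rms0 <- sqrt(mean(nearestNeighbors(applyTransform(init, src), cl)$dist^2))
  expect_lt(res$rms, rms0)

  # disjoint clouds with a tight rejection distance cannot converge
  far <- cl + 100
  expect_error(icpRegister(far, cl, rejectDist = 1), "convergence error")
  expect_error(icpRegister(cl[1:2, ], cl), ">= 3")
})

test_that("scan merging deduplicates within tolerance and degrades to concat", {
  jaw <- twoToothJaw()
  cl <- pointCloud(positions(samplePointsOnMesh(mouthSurfaceMesh(jaw), 2000,
                                                seed = 8)))
  m <- mergeScans(cl, cl, mergeTolerance = 0.1)
  expect_equal(nrow(positions(m)), nrow(positions(cl)))
  m0 <- mergeScans(cl, cl, mergeTolerance = 0)
  expect_equal(nrow(positions(m0)), 2L * nrow(positions(cl)))
  # empty inputs pass through
  emp <- pointCloud(matrix(numeric(0), 0, 3))
  expect_equal(nrow(positions(mergeScans(emp, cl))), nrow(positions(cl)))

  # complementary partial scans: merged coverage exceeds each input's
  imp <- do.call(rbind, lapply(simulateSurfaceScan(jaw, "impression", 8,
                                                   seed = 1,
                                                   pointsPerView = 6000),
                               positions))
  cst <- do.call(rbind, lapply(simulateSurfaceScan(jaw, "cast", 8, seed = 2,
                                                   pointsPerView = 6000),
                               positions))
  merged <- mergeScans(pointCloud(imp), pointCloud(cst),
                       mergeTolerance = 0.05)
  ref <- samplePointsOnMesh(mouthSurfaceMesh(jaw), 15000, seed = 9)
  crownRef <- ref@positions[ref@labels != "gingiva", ]
  expect_gte(surfaceCoverage(crownRef, positions(merged), 0.25), 0.99)
  expect_lt(surfaceCoverage(crownRef, imp, 0.25), 0.99)
  expect_lt(surfaceCoverage(crownRef, cst, 0.25), 0.99)
})

test_that("implicit reconstruction recovers an analytic sphere", {
  set.seed(5)
  u <- matrix(rnorm(3 * 4000), ncol = 3); u <- u / sqrt(rowSums(u^2))
  sph <- pointCloud(6 * u, normals = u)
  mesh <- reconstructMesh(sph, voxelPitch = 0.5)
  rads <- sqrt(rowSums(vertices(mesh)^2))
  expect_lt(max(abs(rads - 6)), 0.5)
  d <- nearestNeighbors(vertices(mesh), positions(sph))$dist
  expect_lte(mean(d), 0.5)

  expect_error(reconstructMesh(pointCloud(matrix(rnorm(30), 10))), ">= 100")
  flat <- cbind(runif(500), runif(500), 0)
  expect_error(reconstructMesh(pointCloud(flat), 0.2), "coplanar")
})

test_that("surface variation matches its eigen definition and limits", {
  # coplanar and isotropic limits
  set.seed(1)
  plane <- cbind(runif(50), runif(50), 0)
  expect_equal(max(abs(deltaN(surfaceVariation(plane, 10)))), 0)
  oct <- rbind(diag(3), -diag(3))
  expect_equal(unique(round(deltaN(surfaceVariation(oct, 3)), 12)),
               round(1 / 3, 12))

  # random neighborhood vs an independent eigen computation from the
  # covariance definition
  nb <- matrix(rnorm(150), ncol = 3)
  cf <- surfaceVariation(nb, radius = 1e3)
  for (i in c(1, 25, 50)) {
    Q <- nb  # every point is a neighbor at this radius
    dev <- sweep(Q, 2, colMeans(Q))
    C <- t(dev) %*% dev
    lam <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(deltaN(cf)[i], lam[1] / sum(lam), tolerance = 1e-12)
  }

  # range invariant and rigid invariance
  jaw <- twoToothJaw()
  cl <- positions(samplePointsOnMesh(mouthSurfaceMesh(jaw), 3000, seed = 2))
  cf1 <- surfaceVariation(cl, 2)
  d1 <- deltaN(cf1)[cf1@defined]
  expect_true(all(d1 >= 0 & d1 <= 1 / 3 + 1e-12))
  tf <- rigidTransform(rotationMatrix(c(1, 1, 0), 33), c(5, -2, 7))
  cf2 <- surfaceVariation(applyTransform(tf, cl), 2)
  expect_lt(max(abs(deltaN(cf2)[cf1@defined] - d1)), 1e-9)

  # fewer than 3 neighbors: flagged undefined, not fatal
  sparse <- surfaceVariation(rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0)), 1)
  expect_false(any(sparse@defined))
})

test_that("margin splines interpolate closed loops and reject bad seeds", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  seeds <- cbind(10 * cos(th), 10 * sin(th), 0)
  mg <- fitMarginSpline(seeds, "11")
  mp <- marginPoints(mg, nOut = 720)
  expect_lt(max(abs(sqrt(rowSums(mp[, 1:2]^2)) - 10)), 1e-3 * 10)
  # a sparser 8-seed loop carries the expected O(h^4) interpolation error
  th8 <- seq(0, 2 * pi, length.out = 9)[-9]
  mg8 <- fitMarginSpline(cbind(10 * cos(th8), 10 * sin(th8), 0), "11")
  mp8 <- marginPoints(mg8, nOut = 720)
  expect_lt(max(abs(sqrt(rowSums(mp8[, 1:2]^2)) - 10)), 2e-3 * 10)
  # closure: position and tangent wrap
  ends <- marginPoints(mg, t = c(0, mg@period))
  expect_lt(max(abs(ends[1, ] - ends[2, ])), 1e-9)
  # evaluating at the knots returns the seeds exactly
  expect_lt(max(abs(marginPoints(mg, t = mg@params) - seeds)), 1e-9)

  expect_error(fitMarginSpline(seeds[1:3, ]), "4 seed")
  bowtie <- rbind(c(0, 0, 0), c(2, 2, 0), c(2, 0, 0), c(0, 2, 0))
  expect_error(fitMarginSpline(bowtie), "self-intersect")
  line <- cbind(1:5, 2 * (1:5), 0 * (1:5))
  expect_error(fitMarginSpline(line), "collinear")
})

test_that("crown/gingiva segmentation matches phantom labels on the ridge", {
  fx <- mouthFixture()
  seg <- fx$segmented
  expect_gte(mean(seg@assignment == fx$mouth@vertexLabels), 0.95)

  # partition: every vertex assigned exactly one label
  expect_equal(length(seg@assignment), nrow(vertices(fx$mouth)))
  expect_true(all(seg@assignment %in%
                    c("gingiva", vapply(fx$jaw@specs, function(s) s@toothId,
                                        character(1)))))

  # each crown sub-mesh is edge-connected
  for (s in fx$jaw@specs) {
    sub <- crownSubMesh(seg, s@toothId)
    comp <- orthofuse:::vertexComponents(sub)
    used <- unique(as.vector(faces(sub)))
    expect_equal(length(unique(comp[used])), 1L)
  }

  # snapped boundary rides the high-curvature ridge
  ed <- orthofuse:::meshEdges(fx$mouth)$edges
  isCrown <- seg@assignment != "gingiva"
  bnd <- unique(c(ed[isCrown[ed[, 1]] & !isCrown[ed[, 2]], 1],
                  ed[!isCrown[ed[, 1]] & isCrown[ed[, 2]], 2]))
  expect_gt(mean(fx$curv@delta[bnd], na.rm = TRUE),
            mean(fx$curv@delta[seg@assignment == "gingiva"], na.rm = TRUE))

  # a margin loop enclosing no vertices is an error naming the tooth
  farLoop <- fitMarginSpline(cbind(c(0, 1, 1, 0) + 500,
                                   c(0, 0, 1, 1) + 500, 0), "48")
  expect_error(segmentCrowns(fx$mouth, fx$curv, list(farLoop)),
               "48")
})
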