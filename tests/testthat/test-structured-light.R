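test_that("stripe pattern sets halve their period and bound their codes", {
  ps <- generatePatterns(5, lh = 64, lv = 16)
  expect_equal(ps@lineCount, 2^5 - 1)
  expect_equal(ps@pointBudget, 64 * 16)
  expect_equal(ps@stripePeriods[3], ps@stripePeriods[2] / 2)
  expect_equal(diff(log2(ps@stripePeriods)), rep(-1, 4))
  expect_error(generatePatterns(0), "1..16")
  expect_error(generatePatterns(17), "1..16")

  # decoded distinct codes never exceed the encoded line budget + 1 slabs
  rig <- makeSimulatedRig(5, imageDim = c(16L, 64L))
  rend <- renderPatternStack(ps, rig, function(x, y) 300 + 0 * x)
  cm <- encodePixels(rend$stack)
  expect_lte(length(unique(cm@codes[cm@valid])), 2^5 - 1)
})

test_that("pixel decoding assembles codes MSB-first and flags low contrast", {
  # pixel 1 bright in all patterns, pixel 4 dark in all, pixels 2-3 mixed
  mk <- function(bits) matrix(bits, 2, 2)
  stack <- list(mk(c(1, 1, 0, 0)), mk(c(1, 0, 1, 0)), mk(c(1, 0, 0, 0)))
  cm <- encodePixels(stack, contrastFloor = 0)
  expect_equal(cm@codes[1, 1], 7L)  # bright in all of n = 3 patterns
  expect_equal(cm@codes[2, 2], 0L)  # dark in all patterns
  expect_equal(cm@codes[1, 2], 2L)  # 010 read MSB-first
  # contrast-free pixels are masked invalid under the default floor
  flat <- encodePixels(stack)
  expect_false(flat@valid[1, 1])
  expect_true(flat@valid[2, 1])
  expect_error(encodePixels(list(mk(0:3), matrix(0, 3, 4))), "shape")
})

test_that("ray-plane triangulation is exact and masks degeneracies", {
  # axis-aligned instance
  rig <- new("ProjectorCameraRig", rayOrigins = matrix(c(0, 0, 0), 1),
             rayDirs = matrix(c(0, 0, 1), 1), imageDim = c(1L, 1L),
             planeNormals = matrix(c(0, 0, 1), 1), planeOffsets = 300,
             workingVolume = rbind(rep(-1e3, 3), rep(1e3, 3)))
  cm <- new("CodeMap", codes = matrix(0L), valid = matrix(TRUE), n = 1L)
  expect_equal(positions(triangulatePoints(cm, rig))[1, ], c(0, 0, 300))

  # random ray/plane pairs vs a closed-form solve
  set.seed(3)
  o <- matrix(runif(45, -50, 50), 15)
  u <- matrix(rnorm(45), 15); u <- u / sqrt(rowSums(u^2))
  nrm <- matrix(rnorm(45), 15); nrm <- nrm / sqrt(rowSums(nrm^2))
  d <- runif(15, -20, 20)
  rig2 <- new("ProjectorCameraRig", rayOrigins = o, rayDirs = u,
              imageDim = c(15L, 1L), planeNormals = nrm, planeOffsets = d,
              workingVolume = rbind(rep(-1e6, 3), rep(1e6, 3)))
  cm2 <- new("CodeMap", codes = matrix(0:14, 15, 1),
             valid = matrix(TRUE, 15, 1), n = 4L)
  got <- positions(triangulatePoints(cm2, rig2))
  oracle <- t(sapply(seq_len(15), function(i) {
    t_ <- (d[i] - sum(nrm[i, ] * o[i, ])) / sum(nrm[i, ] * u[i, ])
    o[i, ] + t_ * u[i, ]
  }))
  expect_lt(max(abs(got - oracle)), 1e-9)

  # ray parallel to its plane: masked and reported, no crash
  rigP <- new("ProjectorCameraRig", rayOrigins = matrix(c(0, 0, 0), 1),
              rayDirs = matrix(c(1, 0, 0), 1), imageDim = c(1L, 1L),
              planeNormals = matrix(c(0, 0, 1), 1), planeOffsets = 300,
              workingVolume = rbind(rep(-1e3, 3), rep(1e3, 3)))
  pcP <- triangulatePoints(cm, rigP)
  expect_equal(nrow(positions(pcP)), 0L)
  expect_equal(pcP@metadata$diagnostics$nParallel, 1L)
})

test_that("render-encode-triangulate round trip reproduces the surface", {
  ps <- generatePatterns(6, lh = 64, lv = 48)
  rig <- makeSimulatedRig(6, imageDim = c(48L, 64L))
  rend <- renderPatternStack(ps, rig, function(x, y) 300 + 0 * x)
  cm <- encodePixels(rend$stack)
  expect_true(all(cm@codes[cm@valid] ==
                    matrix(rend$codes, 48, 64)[cm@valid]))
  pc <- triangulatePoints(cm, rig)
  idx <- pc@metadata$pixelIndex
  expect_lt(max(abs(positions(pc) - rend$truePoints[idx, ])), 1e-6)
})

test_that("turntable composition maps views exactly into the common frame", {
  jaw <- twoToothJaw()
  views <- simulateSurfaceScan(jaw, "cast", viewCount = 2, seed = 3,
                               pointsPerView = 1500)
  expect_error(composeTurntableViews(views, matrix(0, 1, 2)), "angle pair")

  # single view at (0, 0): identity
  one <- composeTurntableViews(views[1], matrix(c(0, 0), 1))
  expect_identical(positions(one), positions(views[[1]]))

  # two noise-free views mapped into their own frames, then composed back
  vf <- lapply(views, function(v)
    applyTransform(invertTransform(v@metadata$viewTransform), v))
  angs <- t(vapply(views, function(v) v@metadata$angles, numeric(2)))
  comp <- composeTurntableViews(vf, angs)
  orig <- do.call(rbind, lapply(views, positions))
  nnr <- nearestNeighbors(positions(comp), orig)
  expect_lt(sqrt(mean(nnr$dist^2)), 1e-6)

  # 16 views spanning 360 degrees cover a closed phantom surface
  crown <- jaw@crownMeshes[[1]]
  ref <- samplePointsOnMesh(crown, 8000, seed = 5)
  caught <- list()
  for (v in 1:16) {
    az <- 360 * (v - 1) / 16
    tilt <- if (v %% 2 == 0) 45 else -20
    dirv <- -c(cos(tilt * pi / 180) * cos(az * pi / 180),
               cos(tilt * pi / 180) * sin(az * pi / 180),
               sin(tilt * pi / 180))
    vis <- as.vector(ref@normals %*% (-dirv)) > 0.15
    caught[[v]] <- ref@positions[vis, , drop = FALSE]
  }
  cover <- surfaceCoverage(samplePointsOnMesh(crown, 5000, seed = 6),
                           do.call(rbind, caught), 0.25)
  expect_gte(cover, 0.99)
})
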