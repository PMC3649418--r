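test_that("jaw phantom is deterministic and self-consistent", {
  jaw <- makeJawPhantom(defaultToothSpecs(3))
  jaw2 <- makeJawPhantom(defaultToothSpecs(3))
  expect_identical(jaw@gingivaMesh@vertices, jaw2@gingivaMesh@vertices)
  expect_identical(jaw@crownMeshes[[2]]@vertices, jaw2@crownMeshes[[2]]@vertices)

  # crown apex is tooth tissue; a point far away is not
  s <- jaw@specs[[1]]
  apex <- applyTransform(s@pose, matrix(c(0, 0, s@crownHeight / 2), 1))
  expect_true(jaw@membership$tooth[[1]](apex))
  expect_false(jaw@membership$tooth[[1]](matrix(c(100, 100, 100), 1)))

  # overlapping placements are rejected naming the pair
  bad <- list(toothPhantomSpec("11", pose = rigidTransform(diag(3), c(0, 0, 0))),
              toothPhantomSpec("12", pose = rigidTransform(diag(3), c(1, 0, 0))))
  expect_error(makeJawPhantom(bad, list(autoPlace = FALSE)), "11.*12|overlap")

  # an explicit sub-bounding-radius gap is accepted and teeth stay disjoint
  r1 <- (4^4 + 3.5^4)^(1 / 4)
  ok <- list(toothPhantomSpec("11", pose = rigidTransform(diag(3), c(0, 0, 0))),
             toothPhantomSpec("12", pose = rigidTransform(
               diag(3), c(2 * r1 + 0.3, 0, 0))))
  jawOk <- makeJawPhantom(ok, list(autoPlace = FALSE))
  pts <- cbind(runif(5000, -10, 20), runif(5000, -8, 8), runif(5000, -14, 9))
  both <- jawOk@membership$tooth[[1]](pts) & jawOk@membership$tooth[[2]](pts)
  expect_equal(sum(both), 0L)
})

test_that("voxelization assigns tissue HU, honors spacing metadata and noise", {
  jaw <- oneToothJaw()
  im0 <- intensityModel(noiseSd = 0, seed = 1)
  vol <- voxelizePhantom(jaw, 0.4, im0)
  expect_equal(spacing(vol), c(0.4, 0.4, 0.4))
  lab <- voxelLabels(vol)
  # noiseless: intensity is exactly the tissue HU everywhere
  expect_true(all(intensities(vol)[lab == 3] == im0@huTooth))
  expect_true(all(intensities(vol)[lab == 2] == im0@huBone))
  expect_true(all(intensities(vol)[lab == 0] == im0@huBackground))
  # ordering of tissue intensities in the noiseless volume
  expect_true(mean(intensities(vol)[lab == 3]) > mean(intensities(vol)[lab == 2]))
  expect_true(mean(intensities(vol)[lab == 2]) > mean(intensities(vol)[lab == 1]))

  # label consistency against the analytic membership at voxel centers
  d <- dim(lab)
  set.seed(4)
  pick <- cbind(sample(d[1], 400, TRUE), sample(d[2], 400, TRUE),
                sample(d[3], 400, TRUE))
  world <- sweep(sweep(pick - 1, 2, spacing(vol), "*"), 2, origin(vol), "+")
  expect_identical(lab[pick], labelPoints(jaw, world))

  # with noise, the tooth-voxel sample mean stays within the LLN band
  sd_ <- 30
  voln <- voxelizePhantom(jaw, 0.4, intensityModel(noiseSd = sd_, seed = 5))
  tv <- intensities(voln)[voxelLabels(voln) == 3]
  expect_lt(abs(mean(tv) - im0@huTooth), 3 * sd_ / sqrt(length(tv)))

  # determinism: same seed, identical arrays
  voln2 <- voxelizePhantom(jaw, 0.4, intensityModel(noiseSd = sd_, seed = 5))
  expect_identical(intensities(voln), intensities(voln2))

  expect_error(voxelizePhantom(jaw, -0.4), "spacing")

  # streak artifacts raise intensity along rays near the metal slice
  vs <- voxelizePhantom(jaw, 0.4, intensityModel(noiseSd = 0, seed = 1,
                                                 streakAmplitude = 400))
  expect_gt(max(intensities(vs) - intensities(vol)), 100)
})

test_that("complementary scans cull the mode-specific bands but cover jointly", {
  jaw <- twoToothJaw()
  imp <- simulateSurfaceScan(jaw, "impression", viewCount = 8, seed = 1,
                             pointsPerView = 6000)
  cst <- simulateSurfaceScan(jaw, "cast", viewCount = 8, seed = 2,
                             pointsPerView = 6000)
  expect_error(simulateSurfaceScan(jaw, "plaster"), "arg")

  expect_equal(sum(unlist(lapply(imp, pointTags)) == "cusp_tip"), 0L)
  expect_equal(sum(unlist(lapply(cst, pointTags)) == "interproximal_wall"), 0L)

  ref <- samplePointsOnMesh(mouthSurfaceMesh(jaw), 20000, seed = 9)
  crownRef <- ref@positions[ref@labels != "gingiva", ]
  impP <- do.call(rbind, lapply(imp, positions))
  cstP <- do.call(rbind, lapply(cst, positions))
  covImp <- surfaceCoverage(crownRef, impP, 0.25)
  covCst <- surfaceCoverage(crownRef, cstP, 0.25)
  covUnion <- surfaceCoverage(crownRef, rbind(impP, cstP), 0.25)
  expect_lt(covImp, 0.99)
  expect_lt(covCst, 0.99)
  expect_gte(covUnion, 0.99)

  # determinism of a view under a fixed seed
  v1 <- simulateSurfaceScan(jaw, "cast", viewCount = 2, seed = 3,
                            pointsPerView = 1000)
  v2 <- simulateSurfaceScan(jaw, "cast", viewCount = 2, seed = 3,
                            pointsPerView = 1000)
  expect_identical(positions(v1[[1]]), positions(v2[[1]]))
})

test_that("analytic oracles integrate to consistent tooth volumes", {
  jaw <- oneToothJaw()
  # Monte Carlo volume vs the quadrature of analytic cross sections
  set.seed(2)
  n <- 200000
  pts <- cbind(runif(n, -6, 6), runif(n, 19, 31), runif(n, -13, 9))
  frac <- mean(jaw@membership$tooth[[1]](pts))
  mc <- frac * 12 * 12 * 22
  expect_lt(abs(mc - jaw@analytic$toothVolume(1)) / jaw@analytic$toothVolume(1),
            0.03)
})
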