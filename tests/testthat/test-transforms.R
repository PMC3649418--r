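test_that("rigid transforms compose, invert and reject reflections", {
  R1 <- rotationMatrix("z", 30)
  tf <- rigidTransform(R1, c(1, -2, 3))
  expect_error(rigidTransform(diag(c(1, 1, -1))), "determinant")

  p <- matrix(rnorm(30), ncol = 3)
  roundTrip <- applyTransform(invertTransform(tf), applyTransform(tf, p))
  expect_lt(max(abs(roundTrip - p)), 1e-12)

  tf2 <- rigidTransform(rotationMatrix("x", -40), c(0, 5, 0))
  ab <- composeTransforms(tf2, tf)
  expect_lt(max(abs(applyTransform(ab, p) -
                      applyTransform(tf2, applyTransform(tf, p)))), 1e-12)
})

test_that("Kabsch fit recovers exact correspondences and fixes reflections", {
  set.seed(11)
  src <- matrix(runif(60, -10, 10), ncol = 3)
  tf <- rigidTransform(rotationMatrix(c(1, 2, 0.5), 55), c(4, -1, 2))
  fit <- fitRigidTransform(src, applyTransform(tf, src))
  expect_lt(max(abs(fit@rotation - tf@rotation)), 1e-10)
  expect_lt(max(abs(fit@translation - tf@translation)), 1e-9)

  # near-planar sets tempt the SVD toward a reflection; det must stay +1
  planar <- cbind(runif(20), runif(20), rnorm(20, sd = 1e-6))
  fit2 <- fitRigidTransform(planar, applyTransform(tf, planar))
  expect_equal(det(fit2@rotation), 1, tolerance = 1e-9)
})
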