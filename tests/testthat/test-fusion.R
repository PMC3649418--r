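test_that("crown geometry is kept verbatim and the fusion is one body", {
  fx <- fusedFixture()
  tm <- fx$tooth
  nvc <- nrow(vertices(fx$crown))
  # every crown vertex present, unmodified, at the same indices
  expect_identical(vertices(tm@fusedMesh)[seq_len(nvc), ],
                   vertices(fx$crown))
  # crown faces carried over with provenance tags
  expect_equal(sum(tm@fusedMesh@faceTags == "optical"),
               nrow(faces(fx$crown)))
  expect_true(all(c("cbct", "seam") %in% tm@fusedMesh@faceTags))
  # single edge-connected component
  comp <- orthofuse:::vertexComponents(tm@fusedMesh)
  used <- unique(as.vector(faces(tm@fusedMesh)))
  expect_equal(length(unique(comp[used])), 1L)

  # area conservation: fused area = crown area + kept-root area + seam area,
  # and the kept-root set is what lies below the crown rim plane
  rim <- vertices(fx$crown)[orthofuse:::.orderedLoops(fx$crown)[[1]], ]
  rimC <- colMeans(rim)
  nrm <- svd(sweep(rim, 2, rimC))$v[, 3]
  if (sum((colMeans(vertices(fx$crown)) - rimC) * nrm) < 0) nrm <- -nrm
  fcs <- orthofuse:::faceCentroids(fx$root)
  below <- as.vector(sweep(fcs, 2, rimC) %*% nrm) < 0
  keptArea <- sum(orthofuse:::faceAreas(fx$root)[below])
  tagArea <- vapply(split(orthofuse:::faceAreas(tm@fusedMesh),
                          tm@fusedMesh@faceTags), sum, numeric(1))
  expect_equal(unname(tagArea["optical"]), meshArea(fx$crown),
               tolerance = 1e-9)
  expect_equal(unname(tagArea["cbct"]), keptArea, tolerance = 0.01)

  # disjoint crown and root cannot be fused
  farRoot <- applyTransform(rigidTransform(diag(3), c(0, 0, -40)), fx$root)
  expect_error(fuseCrownRoot(fx$crown, farRoot), "fusion error")
})

test_that("multi-body model keeps bodies disjoint and separately posed", {
  fx <- fusedFixture()
  jaw <- fx$jaw
  model <- buildOrthodonticModel(list(fx$tooth), jaw@gingivaMesh,
                                 checkCollisions = FALSE)
  expect_equal(length(model@teeth), 1L)

  # zero-teeth model is valid
  m0 <- buildOrthodonticModel(list(), jaw@gingivaMesh,
                              checkCollisions = FALSE)
  expect_equal(length(m0@teeth), 0L)

  # identity transform leaves the model bit-identical
  mId <- transformTooth(model, "11", rigidTransform())
  expect_identical(mId@teeth[[1]]@fusedMesh@vertices,
                   model@teeth[[1]]@fusedMesh@vertices)
  expect_identical(mId@gingiva@vertices, model@gingiva@vertices)

  # T then T^-1 restores vertex positions
  tf <- rigidTransform(rotationMatrix("y", 7), c(1, 2, -0.5))
  m2 <- transformTooth(transformTooth(model, "11", tf), "11",
                       invertTransform(tf))
  p1 <- applyTransform(model@teeth[[1]]@pose, model@teeth[[1]]@fusedMesh)
  p2 <- applyTransform(m2@teeth[[1]]@pose, m2@teeth[[1]]@fusedMesh)
  expect_lt(max(abs(vertices(p1) - vertices(p2))), 1e-9)

  expect_error(transformTooth(model, "48", tf), "unknown tooth")

  # two copies of the tooth side by side: moving one into the other flips
  # exactly that collision pair
  t2 <- fx$tooth
  t2@toothId <- "12"
  t2@pose <- rigidTransform(diag(3), c(11, 0, 0))
  m3 <- buildOrthodonticModel(list(fx$tooth, t2), jaw@gingivaMesh,
                              checkCollisions = TRUE)
  expect_false(any(m3@collisions$colliding))
  m4 <- transformTooth(m3, "12", rigidTransform(diag(3), c(-9, 0, 0)))
  hit <- m4@collisions[m4@collisions$colliding, ]
  expect_equal(nrow(hit), 1L)
  expect_setequal(c(hit$bodyA, hit$bodyB), c("11", "12"))
})

test_that("export writes one STL per body plus a faithful manifest", {
  fx <- fusedFixture()
  model <- buildOrthodonticModel(list(fx$tooth), fx$jaw@gingivaMesh,
                                 checkCollisions = FALSE)
  td <- withr::local_tempdir()
  exportModel(model, td)
  manifest <- jsonlite::read_json(file.path(td, "manifest.json"))
  ids <- unlist(lapply(manifest$bodies, function(b) b$toothId))
  expect_equal(sort(ids), "11")
  expect_equal(manifest$units, "mm")

  back <- importModel(td)
  expect_equal(length(back@teeth), 1L)
  a <- vertices(back@teeth[[1]]@fusedMesh)
  b <- vertices(model@teeth[[1]]@fusedMesh)
  expect_equal(nrow(faces(back@teeth[[1]]@fusedMesh)),
               nrow(faces(model@teeth[[1]]@fusedMesh)))
  expect_lt(max(nearestNeighbors(a, b)$dist), 1e-6)
  expect_lt(max(nearestNeighbors(b, a)$dist), 1e-6)

  # facet normals in the file agree with right-hand winding
  txt <- readLines(file.path(td, "tooth_11.stl"), warn = FALSE)
  nl <- grep("facet normal", txt, value = TRUE)[1:200]
  vl <- grep("^\\s*vertex", txt, value = TRUE)[1:600]
  nrm <- do.call(rbind, lapply(strsplit(trimws(nl), "\\s+"),
                               function(x) as.numeric(x[3:5])))
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  agree <- numeric(0)
  for (i in seq_len(200)) {
    a <- V[3 * i - 2, ]; b <- V[3 * i - 1, ]; c_ <- V[3 * i, ]
    e1 <- b - a; e2 <- c_ - a
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    len <- sqrt(sum(cr^2))
    if (len > 1e-12) agree <- c(agree, sum(nrm[i, ] * cr / len))
  }
  expect_true(all(agree > 0.99))
})
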