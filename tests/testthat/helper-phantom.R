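# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

oneToothJaw <- function() fixture("jaw1", function()
  makeJawPhantom(list(toothPhantomSpec("11"))))

twoToothJaw <- function() fixture("jaw2", function()
  makeJawPhantom(defaultToothSpecs(2)))

# noisy single-tooth volume at CBCT-like resolution, auto bounding box
oneToothVolume <- function(seed = 7, noiseSd = 30) {
  fixture(paste0("vol1_", seed, "_", noiseSd), function()
    voxelizePhantom(oneToothJaw(), 0.4,
                    intensityModel(noiseSd = noiseSd, seed = seed)))
}

mouthFixture <- function() fixture("mouth", function() {
  jaw <- twoToothJaw()
  mouth <- mouthSurfaceMesh(jaw)
  curv <- surfaceVariation(mouth@vertices, radius = 2)
  margins <- lapply(seq_along(jaw@specs), function(i)
    fitMarginSpline(marginSeedPoints(jaw, i), jaw@specs[[i]]@toothId))
  list(jaw = jaw, mouth = mouth, curv = curv, margins = margins,
       segmented = segmentCrowns(mouth, curv, margins))
})

# mean distance from a contour stack to the analytic tooth boundary, per slice
contourOracleDistances <- function(jaw, toothIdx, stack, volume) {
  zs <- origin(volume)[3] +
    (sliceIndices(stack) - 1) * spacing(volume)[3]
  mapply(function(loops, z) {
    pts <- do.call(rbind, loops)
    if (is.null(pts) || !nrow(pts)) return(NA_real_)
    mean(jaw@analytic$contourDistance(toothIdx, cbind(pts, z)))
  }, sliceContours(stack), zs)
}

# rasterized disk image and its edge indicator, shared by the level-set tests
diskImage <- function(n = 64, r = 15, amplitude = 200) {
  matrix(as.numeric(outer(seq_len(n), seq_len(n), function(x, y)
    (x - n / 2)^2 + (y - n / 2)^2) <= r^2), n, n) * amplitude
}

binaryStepField <- function(mask) {
  new("LevelSetField", phi = ifelse(mask, -2, 2) + 0, spacing = c(1, 1),
      iterations = 0L)
}

# An idealized crown/root pair in which the CBCT tooth model is rebuilt from
# the analytic cross-sections, so the optical and CBCT geometry coincide.
fusedFixture <- function() fixture("fused", function() {
  jaw <- oneToothJaw()
  s <- jaw@specs[[1]]
  crown <- crownSubMesh(local({
    mouth <- mouthSurfaceMesh(jaw)
    curv <- surfaceVariation(mouth@vertices, radius = 2)
    segmentCrowns(mouth, curv,
                  list(fitMarginSpline(marginSeedPoints(jaw, 1), "11")))
  }), "11")
  zs <- seq(-s@rootLength + 0.3, s@crownHeight - 0.3, by = 0.4)
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  contours <- lapply(zs, function(zw) {
    zl <- zw - s@pose@translation[3]
    if (zl >= 0) {
      sc <- orthofuse:::.crownScale(zl / s@crownHeight)
      rb <- sc * ((abs(cos(th)) / s@crownRadii[1])^4 +
                    (abs(sin(th)) / s@crownRadii[2])^4)^(-1 / 4)
      list(cbind(rb * cos(th) + s@pose@translation[1],
                 rb * sin(th) + s@pose@translation[2]))
    } else {
      g <- orthofuse:::.rootGeometry(s, -zl / s@rootLength)
      list(cbind(g$radius * cos(th) + s@pose@translation[1],
                 g$radius * sin(th) + s@pose@translation[2]))
    }
  })
  stack <- new("SliceContourStack", toothId = "11",
               sliceIndices = seq_along(zs),
               contours = contours, areas = rep(1, length(zs)),
               spacing = c(0.4, 0.4, 0.4),
               origin = c(0, 0, zs[1]))
  root <- contoursToMesh(stack)
  list(jaw = jaw, crown = crown, root = root,
       tooth = fuseCrownRoot(crown, root, toothId = "11"))
})


# Two-tooth CBCT volume whose field of view contains the whole bone sector
# (the bone envelope cannot be contoured if it is clipped by the image
# border), plus the segmented first tooth.
twoToothVolume <- function() fixture("jaw2vol", function()
  voxelizePhantom(twoToothJaw(), 0.4, intensityModel(noiseSd = 20, seed = 1),
                  bbox = rbind(c(-20, 13, -15.5), c(20, 36, 8.5))))

twoToothStack1 <- function() fixture("jaw2st1", function()
  segmentTooth(twoToothVolume(), twoToothJaw()@crownMeshes[[1]],
               toothId = "11"))

# Bone envelope stack for the two-tooth jaw: manual annular-sector init at a
# mid-bone slice, propagation clamped to the slice range where bone exists.
boneStackFixture <- function() fixture("jaw2bone", function() {
  jaw <- twoToothJaw(); vol <- twoToothVolume(); st1 <- twoToothStack1()
  arch <- jaw@archParameters
  ang <- atan2(vapply(jaw@specs, function(s) s@pose@translation[2], 1),
               vapply(jaw@specs, function(s) s@pose@translation[1], 1))
  thb <- seq(min(ang) - 0.37, max(ang) + 0.37, length.out = 40)
  rOut <- arch$radius + arch$boneHalfWidth + 0.3
  rIn <- arch$radius - arch$boneHalfWidth - 0.3
  poly <- rbind(cbind(rOut * cos(thb), rOut * sin(thb)),
                cbind(rIn * cos(rev(thb)), rIn * sin(rev(thb))))
  zToIdx <- function(z) round((z - origin(vol)[3]) / spacing(vol)[3]) + 1L
  suppressWarnings(
    segmentBone(vol, manualInit = list(contour = poly,
                                       startSlice = zToIdx(-6),
                                       direction = -1L),
                toothStacks = list(st1), dilationRadius = 1L,
                sliceRange = c(zToIdx(-13.5), zToIdx(-0.4))))
})
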