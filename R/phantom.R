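# Synthetic jaw phantoms. Tooth crowns are superellipsoid-profile solids and
# roots are tapered capsules with a rounded apex; every cross section
# perpendicular to the tooth axis is closed-form, which is what makes the
# phantom usable as segmentation ground truth. Teeth are placed on an arch,
# wrapped in a gingiva sheet and embedded in an alveolar bone slab.

.seExponent <- 4
.neckScale <- 0.55   # crown cross-section scale at the cemento-enamel junction
.neckBlendU <- 0.3   # fraction of crown height over which the neck blends out

# Area of the superellipse |x/a|^p + |y/b|^p <= 1.
.seArea <- function(a, b, p = .seExponent)
  4 * a * b * gamma(1 + 1 / p)^2 / gamma(1 + 2 / p)

# Crown cross-section scale factor at relative height u = z / crownHeight.
.crownScale <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  blend <- ifelse(u >= .neckBlendU, 1,
                  .neckScale + (1 - .neckScale) * u / .neckBlendU)
  sqrt(pmax(0, 1 - u^2)) * blend
}

# Root layout at relative depth s = -z / rootLength, in the tooth frame.
.rootGeometry <- function(spec, s) {
  a <- spec@crownRadii[1]; b <- spec@crownRadii[2]
  mn <- min(a, b); k <- spec@rootCount
  base <- switch(as.character(k),
    "1" = list(r0 = 0.85 * .neckScale * mn, centers = matrix(c(0, 0), 1)),
    "2" = list(r0 = 0.60 * .neckScale * mn,
               centers = matrix(c(-1, 0, 1, 0), 2, byrow = TRUE)),
    "3" = list(r0 = 0.50 * .neckScale * mn,
               centers = matrix(c(-1, 0, 1, 0, 0, 1), 3, byrow = TRUE)))
  dmax <- 0.75 * .neckScale * a
  spread <- dmax * pmin(1, s / 0.35)
  radius <- base$r0 * (1 - spec@rootTaper * s) * sqrt(pmax(0, 1 - s^6))
  list(centers = base$centers, spread = spread, radius = radius)
}

#' Construct a tooth phantom specification
#'
#' @param toothId ISO 3950 code.
#' @param crownHeight crown height, mm.
#' @param crownRadii superellipsoid semi-axes (a, b), mm.
#' @param rootCount 1, 2 or 3 roots.
#' @param rootLength mm.
#' @param rootTaper radius reduction fraction at the apex, in (0, 1).
#' @param pose rigid placement (rotation about the tooth axis + translation).
#' @export
toothPhantomSpec <- function(toothId, crownHeight = 8, crownRadii = c(4, 3.5),
                             rootCount = 1L, rootLength = 12,
                             rootTaper = 0.7, pose = rigidTransform()) {
  new("ToothPhantomSpec", toothId = toothId, crownHeight = crownHeight,
      crownRadii = crownRadii, rootCount = as.integer(rootCount),
      rootLength = rootLength, rootTaper = rootTaper, pose = pose)
}

# Maximal xy extent of a tooth (superellipse corner radius).
.toothBoundingRadius <- function(spec)
  (spec@crownRadii[1]^4 + spec@crownRadii[2]^4)^(1 / 4)

# World -> tooth-local coordinates.
.toLocal <- function(spec, pts)
  applyTransform(invertTransform(spec@pose), pts)

# Vectorized inside test in tooth-local coordinates.
.toothInsideLocal <- function(spec, pts) {
  a <- spec@crownRadii[1]; b <- spec@crownRadii[2]
  h <- spec@crownHeight; L <- spec@rootLength
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  inside <- rep(FALSE, nrow(pts))
  crown <- z >= 0 & z <= h
  if (any(crown)) {
    sv <- ((abs(x[crown]) / a)^.seExponent +
             (abs(y[crown]) / b)^.seExponent)^(1 / .seExponent)
    inside[crown] <- sv <= .crownScale(z[crown] / h)
  }
  root <- z < 0 & z >= -L
  if (any(root)) {
    s <- -z[root] / L
    g <- .rootGeometry(spec, s)
    hit <- rep(FALSE, sum(root))
    for (j in seq_len(nrow(g$centers))) {
      cx <- g$centers[j, 1] * g$spread
      cy <- g$centers[j, 2] * g$spread
      hit <- hit | (x[root] - cx)^2 + (y[root] - cy)^2 <= g$radius^2
    }
    inside[root] <- hit
  }
  inside
}

# Cross-section area (mm^2) at tooth-local height z.
.toothSectionArea <- function(spec, z) {
  a <- spec@crownRadii[1]; b <- spec@crownRadii[2]
  h <- spec@crownHeight; L <- spec@rootLength
  vapply(z, function(zz) {
    if (zz >= 0 && zz <= h) {
      .seArea(a, b) * .crownScale(zz / h)^2
    } else if (zz < 0 && zz >= -L) {
      s <- -zz / L
      g <- .rootGeometry(spec, s)
      k <- nrow(g$centers)
      area <- k * pi * g$radius^2
      if (k > 1 && g$radius > 0) {
        # subtract pairwise lens overlaps (inclusion-exclusion, disjoint pairs)
        for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
          d <- sqrt(sum((g$centers[i, ] - g$centers[j, ])^2)) * g$spread
          r <- g$radius
          if (d < 2 * r) {
            lens <- 2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
            area <- area - lens
          }
        }
      }
      area
    } else 0
  }, numeric(1))
}

# Distance of slice points (tooth-local, common z) to the analytic
# cross-section boundary.
.toothContourDistance <- function(spec, pts) {
  a <- spec@crownRadii[1]; b <- spec@crownRadii[2]
  h <- spec@crownHeight; L <- spec@rootLength
  z <- pts[1, 3]
  x <- pts[, 1]; y <- pts[, 2]
  if (z >= 0) {
    s <- .crownScale(z / h)
    th <- atan2(y, x)
    rb <- s * ((abs(cos(th)) / a)^.seExponent +
                 (abs(sin(th)) / b)^.seExponent)^(-1 / .seExponent)
    abs(sqrt(x^2 + y^2) - rb)
  } else {
    g <- .rootGeometry(spec, -z / L)
    d <- rep(Inf, length(x))
    for (j in seq_len(nrow(g$centers))) {
      cx <- g$centers[j, 1] * g$spread; cy <- g$centers[j, 2] * g$spread
      d <- pmin(d, abs(sqrt((x - cx)^2 + (y - cy)^2) - g$radius))
    }
    d
  }
}

# Tessellated crown surface (full crown, local z in [0, crownHeight]).
.crownSurfaceMesh <- function(spec, uFrom = 0, nTheta = 48L, nU = 24L) {
  a <- spec@crownRadii[1]; b <- spec@crownRadii[2]; h <- spec@crownHeight
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  us <- seq(uFrom, 0.995, length.out = nU)
  e <- 2 / .seExponent
  ring <- function(u) {
    s <- .crownScale(u)
    cbind(a * s * sign(cos(th)) * abs(cos(th))^e,
          b * s * sign(sin(th)) * abs(sin(th))^e,
          rep(u * h, nTheta))
  }
  V <- do.call(rbind, lapply(us, ring))
  apex <- c(0, 0, h)
  V <- rbind(V, apex)
  nv <- nrow(V)
  F <- list()
  for (i in seq_len(nU - 1L)) {
    b0 <- (i - 1L) * nTheta
    j <- seq_len(nTheta); j2 <- c(seq_len(nTheta)[-1], 1L)
    F[[i]] <- rbind(cbind(b0 + j, b0 + j2, b0 + nTheta + j),
                    cbind(b0 + j2, b0 + nTheta + j2, b0 + nTheta + j))
  }
  top <- (nU - 1L) * nTheta
  j <- seq_len(nTheta); j2 <- c(seq_len(nTheta)[-1], 1L)
  F[[nU]] <- cbind(top + j, top + j2, nv)
  mesh <- triangleMesh(applyTransform(spec@pose, V), do.call(rbind, F),
                       vertexLabels = rep(spec@toothId, nv))
  mesh
}

# Gingiva sheet: a ridge band following the arch with a collar rising to the
# margin height around each tooth; cells under the teeth are removed.
.gingivaMesh <- function(specs, arch) {
  R <- arch$radius; hw <- arch$gingivaHalfWidth; zm <- arch$marginHeight
  centers <- t(vapply(specs, function(s) s@pose@translation, numeric(3)))
  angs <- atan2(centers[, 2], centers[, 1])
  thr <- range(angs) + c(-0.25, 0.25)
  th <- seq(thr[1], thr[2], length.out = 160L)
  dd <- seq(-hw, hw, length.out = 22L)
  g <- expand.grid(th = th, d = dd)
  px <- (R + g$d) * cos(g$th); py <- (R + g$d) * sin(g$th)
  # gentle smooth ridge away from the teeth ...
  pz <- 0.8 * exp(-(g$d / hw)^2)
  # ... with a steep collar rising to just below the margin at each crown
  # wall, so the margin line is the sharpest crease on the model
  insideAny <- rep(FALSE, length(px))
  for (s in specs) {
    loc <- .toLocal(s, cbind(px, py, 0))
    sv <- ((abs(loc[, 1]) / s@crownRadii[1])^4 +
             (abs(loc[, 2]) / s@crownRadii[2])^4)^(1 / 4)
    near <- pmin(1, pmax(0, (1.35 - sv) / 0.35))
    pz <- pmax(pz, (zm - 0.05) * sqrt(near))
    insideAny <- insideAny | sv < 0.92 * .crownScale(zm / s@crownHeight)
  }
  V <- cbind(px, py, pz)
  nTh <- length(th); nD <- length(dd)
  idx <- function(i, j) (j - 1L) * nTh + i
  F <- list()
  for (j in seq_len(nD - 1L)) for (i in seq_len(nTh - 1L)) {
    quad <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    if (any(insideAny[quad])) next
    F[[length(F) + 1L]] <- rbind(quad[c(1, 2, 3)], quad[c(1, 3, 4)])
  }
  triangleMesh(V, do.call(rbind, F),
               vertexLabels = rep("gingiva", nrow(V)))
}

#' Default tooth specifications for a synthetic arch
#' @param nTeeth number of teeth (<= 8).
#' @export
defaultToothSpecs <- function(nTeeth = 4L) {
  ids <- c("11", "12", "13", "14", "21", "22", "23", "24")[seq_len(nTeeth)]
  lapply(seq_len(nTeeth), function(i)
    toothPhantomSpec(ids[i],
                     crownHeight = 8 - 0.3 * (i %% 3),
                     crownRadii = c(4 - 0.25 * (i %% 2), 3.5 - 0.2 * (i %% 3)),
                     rootCount = 1L, rootLength = 12 - 0.5 * (i %% 2),
                     rootTaper = 0.7))
}

#' Build a jaw phantom
#'
#' Places tooth specifications on an arch (unless they carry explicit poses),
#' builds crown and gingiva meshes with ground-truth vertex labels, and
#' closes over the analytic membership/area/volume functions used as oracles.
#'
#' @param specs list of \linkS4class{ToothPhantomSpec}.
#' @param archParameters list: \code{radius} (mm), \code{gap} (interproximal
#'   gap, mm), \code{gingivaHalfWidth} (mm), \code{marginHeight} (mm),
#'   \code{boneHalfWidth} (mm), \code{autoPlace} (logical).
#' @return a \linkS4class{JawPhantom}.
#' @export
makeJawPhantom <- function(specs, archParameters = list()) {
  if (!length(specs)) stop("need at least one tooth spec")
  arch <- utils::modifyList(list(radius = 25, gap = 0.8, gingivaHalfWidth = 5,
                                 marginHeight = 1, boneHalfWidth = 6,
                                 autoPlace = NULL), archParameters)
  autoPlace <- arch$autoPlace
  if (is.null(autoPlace))
    autoPlace <- all(vapply(specs, function(s)
      max(abs(s@pose@rotation - diag(3))) < 1e-12 &&
        all(s@pose@translation == 0), logical(1)))
  if (autoPlace) {
    R <- arch$radius
    radii <- vapply(specs, .toothBoundingRadius, numeric(1))
    ang <- numeric(length(specs))
    for (i in seq_along(specs)[-1]) {
      chord <- radii[i - 1] + radii[i] + arch$gap
      ang[i] <- ang[i - 1] + 2 * asin(min(1, chord / (2 * R)))
    }
    ang <- ang - mean(ang) + pi / 2  # centered on the +y side of the arch
    for (i in seq_along(specs)) {
      rot <- rotationMatrix("z", ang[i] * 180 / pi + 90)
      specs[[i]]@pose <- rigidTransform(rot, c(R * cos(ang[i]),
                                               R * sin(ang[i]), 0))
    }
  }
  # non-interpenetration (conservative bounding-radius test)
  centers <- t(vapply(specs, function(s) s@pose@translation, numeric(3)))
  radii <- vapply(specs, .toothBoundingRadius, numeric(1))
  for (i in seq_along(specs)) for (j in seq_len(i - 1L)) {
    d <- sqrt(sum((centers[i, 1:2] - centers[j, 1:2])^2))
    if (d < radii[i] + radii[j] - 1e-9)
      stop(sprintf("placement error: teeth %s and %s overlap",
                   specs[[j]]@toothId, specs[[i]]@toothId))
  }
  arch$centerAngle <- atan2(mean(centers[, 2]), mean(centers[, 1]))

  crownMeshes <- lapply(specs, .crownSurfaceMesh)
  ging <- .gingivaMesh(specs, arch)

  boneDepth <- max(vapply(specs, function(s) s@rootLength, numeric(1))) + 3
  toothAngles <- atan2(centers[, 2], centers[, 1])
  sector <- range(toothAngles) + c(-0.35, 0.35)
  inSector <- function(pts) {
    a <- atan2(pts[, 2], pts[, 1])
    a >= sector[1] & a <= sector[2]
  }
  boneMember <- function(pts) {
    d <- abs(sqrt(pts[, 1]^2 + pts[, 2]^2) - arch$radius)
    d <= arch$boneHalfWidth & pts[, 3] <= 0 & pts[, 3] >= -boneDepth &
      inSector(pts)
  }
  softMember <- function(pts) {
    d <- abs(sqrt(pts[, 1]^2 + pts[, 2]^2) - arch$radius)
    d <= arch$boneHalfWidth + 2 & pts[, 3] <= arch$marginHeight + 1 &
      pts[, 3] >= -boneDepth - 2 & inSector(pts)
  }
  toothMember <- lapply(specs, function(s)
    local({ sp <- s; function(pts) .toothInsideLocal(sp, .toLocal(sp, pts)) }))

  analytic <- list(
    crossSectionArea = function(i, zWorld) {
      zl <- zWorld - specs[[i]]@pose@translation[3]
      .toothSectionArea(specs[[i]], zl)
    },
    toothVolume = function(i) {
      s <- specs[[i]]
      stats::integrate(function(z) .toothSectionArea(s, z),
                       -s@rootLength, s@crownHeight,
                       subdivisions = 2000L, rel.tol = 1e-9)$value
    },
    contourDistance = function(i, ptsWorld) {
      .toothContourDistance(specs[[i]], .toLocal(specs[[i]], ptsWorld))
    },
    furcationZ = function(i) {
      s <- specs[[i]]
      if (s@rootCount < 2L) return(NA_real_)
      f <- function(ss) {
        g <- .rootGeometry(s, ss)
        g$spread * sqrt(sum((g$centers[1, ] - g$centers[2, ])^2)) / 2 - g$radius
      }
      ss <- stats::uniroot(f, c(1e-6, 0.9))$root
      specs[[i]]@pose@translation[3] - ss * s@rootLength
    },
    boneDepth = boneDepth)

  new("JawPhantom", specs = specs, archParameters = arch, gingivaMesh = ging,
      crownMeshes = crownMeshes,
      membership = list(tooth = toothMember, bone = boneMember,
                        soft = softMember),
      analytic = analytic)
}

#' Ground-truth tissue label for arbitrary world points
#'
#' 0 = background, 1 = soft tissue, 2 = bone, 2 + i = tooth i (priority
#' tooth > bone > soft).
#' @param jaw a \linkS4class{JawPhantom}.
#' @param pts N x 3 world points, mm.
#' @export
labelPoints <- function(jaw, pts) {
  lab <- integer(nrow(pts))
  lab[jaw@membership$soft(pts)] <- 1L
  lab[jaw@membership$bone(pts)] <- 2L
  for (i in seq_along(jaw@membership$tooth))
    lab[jaw@membership$tooth[[i]](pts)] <- 2L + i
  lab
}

#' Intensity model constructor
#' @param huBackground,huSoftTissue,huBone,huTooth tissue intensities (HU).
#' @param noiseSd Gaussian noise SD, HU.
#' @param streakAmplitude streak artifact amplitude, HU (0 = off).
#' @param seed integer seed.
#' @export
intensityModel <- function(huBackground = 0, huSoftTissue = 300,
                           huBone = 900, huTooth = 1500, noiseSd = 30,
                           streakAmplitude = 0, seed = 1L) {
  new("IntensityModel", huBackground = huBackground,
      huSoftTissue = huSoftTissue, huBone = huBone, huTooth = huTooth,
      noiseSd = noiseSd, streakAmplitude = streakAmplitude,
      seed = as.integer(seed))
}

#' Voxelize a jaw phantom into a CBCT-like volume
#'
#' Each voxel takes the HU of the tissue at its center plus Gaussian noise;
#' optional streak artifacts are added as attenuated rays through a "metal"
#' point at the first tooth's crown. The ground-truth label grid travels in
#' the \code{labels} slot.
#'
#' @param jaw a \linkS4class{JawPhantom}.
#' @param spacing voxel spacing, mm (length 1 or 3).
#' @param intensity an \linkS4class{IntensityModel}.
#' @param margin bounding-box margin, mm.
#' @param bbox optional 2 x 3 matrix (min row, max row) overriding the
#'   automatic extent.
#' @return a \linkS4class{VoxelVolume} with labels.
#' @export
voxelizePhantom <- function(jaw, spacing = c(0.4, 0.4, 0.4),
                            intensity = intensityModel(), margin = 2,
                            bbox = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (is.null(bbox)) {
    centers <- t(vapply(jaw@specs, function(s) s@pose@translation, numeric(3)))
    radii <- vapply(jaw@specs, .toothBoundingRadius, numeric(1))
    hmax <- max(vapply(jaw@specs, function(s) s@crownHeight, numeric(1)))
    bbox <- rbind(c(min(centers[, 1] - radii), min(centers[, 2] - radii),
                    -jaw@analytic$boneDepth),
                  c(max(centers[, 1] + radii), max(centers[, 2] + radii),
                    hmax))
    bbox[1, ] <- bbox[1, ] - margin
    bbox[2, ] <- bbox[2, ] + margin
  }
  dims <- pmax(2L, as.integer(ceiling((bbox[2, ] - bbox[1, ]) / spacing)) + 1L)
  org <- bbox[1, ]
  xs <- org[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- org[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- org[3] + (seq_len(dims[3]) - 1) * spacing[3]
  pts <- cbind(rep(xs, times = dims[2] * dims[3]),
               rep(rep(ys, each = dims[1]), times = dims[3]),
               rep(zs, each = dims[1] * dims[2]))
  lab <- labelPoints(jaw, pts)
  hu <- c(intensity@huBackground, intensity@huSoftTissue, intensity@huBone,
          rep(intensity@huTooth, length(jaw@specs)))[lab + 1L]
  set.seed(intensity@seed)
  if (intensity@noiseSd > 0)
    hu <- hu + rnorm(length(hu), sd = intensity@noiseSd)
  a <- array(hu, dims)
  if (intensity@streakAmplitude > 0) {
    s1 <- jaw@specs[[1]]
    metal <- s1@pose@translation + c(0, 0, s1@crownHeight - 1.5)
    izs <- which(abs(zs - metal[3]) <= 1.5 * spacing[3])
    angles <- seq(0, pi, length.out = 9L)[-9L]
    gx <- rep(xs, times = dims[2]) - metal[1]
    gy <- rep(ys, each = dims[1]) - metal[2]
    rad <- sqrt(gx^2 + gy^2)
    streak <- numeric(length(gx))
    for (an in angles) {
      dperp <- abs(-sin(an) * gx + cos(an) * gy)
      streak <- streak + exp(-(dperp / 0.7)^2)
    }
    streak <- intensity@streakAmplitude * streak / (1 + rad / 5)
    for (iz in izs) a[, , iz] <- a[, , iz] + matrix(streak, dims[1], dims[2])
  }
  new("VoxelVolume", intensities = a, spacing = spacing, origin = org,
      labels = array(lab, dims))
}

#' Combined crown + gingiva "digital mouth" mesh with ground-truth labels
#'
#' Visible crown surfaces (above the gingival margin) concatenated with the
#' gingiva sheet; vertex labels are the tooth id or "gingiva".
#' @param jaw a \linkS4class{JawPhantom}.
#' @export
mouthSurfaceMesh <- function(jaw) {
  zm <- jaw@archParameters$marginHeight
  parts <- lapply(seq_along(jaw@specs), function(i) {
    s <- jaw@specs[[i]]
    .crownSurfaceMesh(s, uFrom = zm / s@crownHeight)
  })
  parts <- c(parts, list(jaw@gingivaMesh))
  V <- do.call(rbind, lapply(parts, function(m) m@vertices))
  offs <- cumsum(c(0L, vapply(parts, function(m) nrow(m@vertices), integer(1))))
  F <- do.call(rbind, lapply(seq_along(parts), function(i)
    parts[[i]]@faces + offs[i]))
  labs <- unlist(lapply(parts, function(m) m@vertexLabels))
  triangleMesh(V, F, vertexLabels = labs)
}

#' Margin-line seed points around one tooth (replaces manual selection)
#'
#' Evenly spaced points on the crown boundary at the gingival margin height,
#' in loop order.
#' @param jaw a \linkS4class{JawPhantom}.
#' @param i tooth index.
#' @param k number of seed points.
#' @export
marginSeedPoints <- function(jaw, i, k = 8L) {
  s <- jaw@specs[[i]]
  zm <- jaw@archParameters$marginHeight
  sc <- .crownScale(zm / s@crownHeight)
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  rb <- sc * ((abs(cos(th)) / s@crownRadii[1])^4 +
                (abs(sin(th)) / s@crownRadii[2])^4)^(-1 / 4)
  applyTransform(s@pose, cbind(rb * cos(th), rb * sin(th), rep(zm, k)))
}

# Tag sampled mouth points with scan-relevant ground truth.
.scanTags <- function(jaw, cloud) {
  P <- cloud@positions
  labs <- cloud@labels
  tags <- rep("", nrow(P))
  for (i in seq_along(jaw@specs)) {
    s <- jaw@specs[[i]]
    mine <- which(labs == s@toothId)
    if (!length(mine)) next
    loc <- .toLocal(s, P[mine, , drop = FALSE])
    tags[mine][loc[, 3] > s@crownHeight - 1.2] <- "cusp_tip"
    low <- loc[, 3] < 0.7 * s@crownHeight
    for (j in seq_along(jaw@specs)) {
      if (j == i) next
      sj <- jaw@specs[[j]]
      lj <- .toLocal(sj, P[mine, , drop = FALSE])
      sv <- ((abs(lj[, 1]) / sj@crownRadii[1])^4 +
               (abs(lj[, 2]) / sj@crownRadii[2])^4)^(1 / 4)
      wall <- low & sv < 1.5 & tags[mine] == ""
      tags[mine][wall] <- "interproximal_wall"
    }
  }
  tags
}

#' Simulate complementary partial-coverage surface scans
#'
#' Emulates the two optical acquisition routes: scanning the inner surface of
#' the mouth impression captures interproximal walls but misses cusp tips
#' (material cannot reach them), while scanning the plaster cast captures
#' cusp tops but misses interproximal walls (optical undercuts). Each view is
#' a visibility-culled surface sample from one direction.
#'
#' @param jaw a \linkS4class{JawPhantom}.
#' @param mode "impression" or "cast".
#' @param viewCount number of turntable views (>= 1).
#' @param noiseSd additive point noise SD, mm.
#' @param seed integer seed.
#' @param pointsPerView surface samples drawn per view.
#' @return list of \linkS4class{PointCloud}s in the common frame; each
#'   carries \code{metadata$viewTransform} (view frame -> common frame) and
#'   \code{metadata$angles} (rotation, tilt in degrees).
#' @export
simulateSurfaceScan <- function(jaw, mode = c("impression", "cast"),
                                viewCount = 8L, noiseSd = 0, seed = 1L,
                                pointsPerView = 6000L) {
  mode <- match.arg(mode)
  if (viewCount < 1L) stop("viewCount must be >= 1")
  mouth <- mouthSurfaceMesh(jaw)
  views <- vector("list", viewCount)
  for (v in seq_len(viewCount)) {
    azimuth <- 360 * (v - 1) / viewCount
    tilt <- if (v %% 2 == 0) 60 else 25
    dir <- -c(cos(tilt * pi / 180) * cos(azimuth * pi / 180),
              cos(tilt * pi / 180) * sin(azimuth * pi / 180),
              sin(tilt * pi / 180))
    cl <- samplePointsOnMesh(mouth, pointsPerView, seed = seed + 1000L * v)
    vis <- as.vector(cl@normals %*% (-dir)) > 0.15
    cl <- pointCloud(cl@positions[vis, , drop = FALSE],
                     normals = cl@normals[vis, , drop = FALSE],
                     labels = cl@labels[vis])
    tags <- .scanTags(jaw, cl)
    keep <- if (mode == "impression") tags != "cusp_tip"
            else tags != "interproximal_wall"
    P <- cl@positions[keep, , drop = FALSE]
    if (noiseSd > 0) {
      set.seed(seed + 7000L * v)
      P <- P + matrix(rnorm(length(P), sd = noiseSd), ncol = 3L)
    }
    # turntable model: p_common = Rz(azimuth) Ry(tilt) p_view
    tf <- rigidTransform(rotationMatrix("z", azimuth) %*%
                           rotationMatrix("y", tilt), c(0, 0, 0))
    views[[v]] <- pointCloud(P,
                             normals = cl@normals[keep, , drop = FALSE],
                             labels = cl@labels[keep], tags = tags[keep],
                             metadata = list(viewTransform = tf,
                                             angles = c(azimuth, tilt),
                                             mode = mode))
  }
  views
}
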