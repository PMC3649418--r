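#' @import methods
#' @importFrom stats rnorm runif splinefun integrate median sd
#' @importFrom grDevices contourLines
#' @importFrom utils head tail
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

#' Rigid transform in 3D
#'
#' A proper rigid-body motion: \code{x -> R x + t} with \code{R} a rotation
#' matrix (orthonormal, determinant +1) and \code{t} a translation in mm.
#'
#' @slot rotation 3x3 rotation matrix.
#' @slot translation length-3 numeric, mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
    if (length(object@translation) != 3L) return("translation must be length 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      return("rotation is not orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      return("rotation determinant is not +1 (reflection?)")
    TRUE
  })

#' Point cloud in mm
#'
#' Positions with optional unit normals and per-point labels/tags. The
#' currency of the optical-scan side of the pipeline.
#'
#' @slot positions N x 3 matrix, mm.
#' @slot normals N x 3 matrix of unit vectors, or NULL.
#' @slot labels character vector of per-point labels (e.g. tooth id or
#'   "gingiva"), or NULL.
#' @slot tags character vector of per-point ground-truth tags (e.g.
#'   "cusp_tip", "interproximal_wall"), or NULL.
#' @slot metadata list of provenance information.
#' @export
setClass("PointCloud",
  representation(positions = "matrix", normals = "matrixOrNULL",
                 labels = "characterOrNULL", tags = "characterOrNULL",
                 metadata = "list"),
  prototype(normals = NULL, labels = NULL, tags = NULL, metadata = list()),
  validity = function(object) {
    P <- object@positions
    if (ncol(P) != 3L) return("positions must be N x 3")
    if (!all(is.finite(P))) return("positions must be finite")
    if (!is.null(object@normals)) {
      if (!all(dim(object@normals) == dim(P)))
        return("normals must match positions")
      nn <- sqrt(rowSums(object@normals^2))
      if (any(abs(nn - 1) > 1e-6)) return("normals must be unit length")
    }
    if (!is.null(object@labels) && length(object@labels) != nrow(P))
      return("labels length must match point count")
    if (!is.null(object@tags) && length(object@tags) != nrow(P))
      return("tags length must match point count")
    TRUE
  })

#' Triangle mesh in mm
#'
#' @slot vertices N x 3 matrix, mm.
#' @slot faces M x 3 integer matrix of 1-based vertex indices.
#' @slot vertexLabels optional per-vertex labels.
#' @slot faceTags optional per-face provenance tags.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexLabels = "characterOrNULL",
                 faceTags = "characterOrNULL"),
  prototype(vertexLabels = NULL, faceTags = NULL),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must be N x 3")
    if (ncol(object@faces) != 3L) return("faces must be M x 3")
    if (nrow(object@faces) > 0) {
      f <- object@faces
      if (min(f) < 1 || max(f) > nrow(object@vertices))
        return("face indices out of range")
    }
    if (!is.null(object@vertexLabels) &&
        length(object@vertexLabels) != nrow(object@vertices))
      return("vertexLabels length mismatch")
    if (!is.null(object@faceTags) &&
        length(object@faceTags) != nrow(object@faces))
      return("faceTags length mismatch")
    TRUE
  })

#' Voxel volume (CBCT-like intensity grid)
#'
#' Intensities are HU-like; world coordinates follow the center-of-voxel
#' convention \code{world = origin + (index - 1) * spacing} with 1-based
#' indices. Axis 3 is the slice (stack) axis.
#'
#' @slot intensities 3D numeric array.
#' @slot spacing length-3 voxel spacing, mm.
#' @slot origin world position of voxel (1,1,1) center, mm.
#' @slot labels optional 3D integer array of ground-truth tissue codes
#'   (0 background, 1 soft tissue, 2 bone, 3+ tooth index + 2).
#' @export
setClass("VoxelVolume",
  representation(intensities = "array", spacing = "numeric",
                 origin = "numeric", labels = "arrayOrNULL"),
  prototype(labels = NULL),
  validity = function(object) {
    if (length(dim(object@intensities)) != 3L)
      return("intensities must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values")
    if (length(object@origin) != 3L) return("origin must be length 3")
    if (!all(is.finite(object@intensities))) return("intensities must be finite")
    if (!is.null(object@labels) &&
        !all(dim(object@labels) == dim(object@intensities)))
      return("labels must match intensity dimensions")
    TRUE
  })

#' Level-set field on one slice
#'
#' Signed function phi on the slice pixel grid; the segmenting contour is the
#' zero level. Convention: negative inside the contour, positive outside.
#'
#' @slot phi 2D numeric matrix.
#' @slot spacing length-2 in-slice pixel spacing, mm.
#' @slot iterations number of evolution iterations applied so far.
#' @export
setClass("LevelSetField",
  representation(phi = "matrix", spacing = "numeric", iterations = "integer"),
  prototype(iterations = 0L),
  validity = function(object) {
    if (!all(is.finite(object@phi))) return("phi must be finite")
    if (length(object@spacing) != 2L || any(object@spacing <= 0))
      return("spacing must be 2 positive values")
    TRUE
  })

#' DRLSE evolution parameters
#'
#' @slot mu distance-regularization weight (>= 0); stability requires
#'   \code{timeStep * mu < 0.25}.
#' @slot lambda edge-length (smoothness) weight, > 0.
#' @slot alpha signed area/balloon weight; positive shrinks a contour
#'   initialized outside the target, negative expands one initialized inside.
#' @slot sigma Gaussian smoothing SD for the edge indicator, pixels.
#' @slot epsilon width of the smoothed Dirac/Heaviside, pixels.
#' @slot timeStep explicit Euler time step.
#' @slot iterations iterations per slice during propagation.
#' @slot firstSliceIterations iterations on the initial slice.
#' @slot tol convergence tolerance on zero-level movement (pixels changed).
#' @export
setClass("DrlseParams",
  representation(mu = "numeric", lambda = "numeric", alpha = "numeric",
                 sigma = "numeric", epsilon = "numeric", timeStep = "numeric",
                 iterations = "integer", firstSliceIterations = "integer",
                 tol = "numeric"),
  validity = function(object) {
    if (object@mu < 0) return("mu must be >= 0")
    if (object@lambda <= 0) return("lambda must be > 0")
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@timeStep <= 0) return("timeStep must be > 0")
    if (object@epsilon <= 0) return("epsilon must be > 0")
    TRUE
  })

#' Per-slice contour stack for one segmented body
#'
#' @slot toothId body identifier (ISO 3950 code or "bone").
#' @slot sliceIndices integer slice indices (stack axis, 1-based).
#' @slot contours list (one per slice) of lists of closed K x 2 polygon
#'   matrices in world mm (in-slice x, y).
#' @slot areas numeric per-slice segmented area, mm^2.
#' @slot spacing volume spacing, mm.
#' @slot origin volume origin, mm.
#' @export
setClass("SliceContourStack",
  representation(toothId = "character", sliceIndices = "integer",
                 contours = "list", areas = "numeric", spacing = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    if (length(object@contours) != length(object@sliceIndices))
      return("one contour list per slice index required")
    TRUE
  })

#' Threshold sweep result
#'
#' @slot thresholds HU thresholds swept.
#' @slot meanDiscrepancy per-threshold mean crown-to-isosurface distance, mm.
#' @slot sdDiscrepancy per-threshold SD of the discrepancy, mm.
#' @slot tauOpt threshold attaining the minimal mean discrepancy (ties broken
#'   toward the lower threshold).
#' @export
setClass("ThresholdSweepResult",
  representation(thresholds = "numeric", meanDiscrepancy = "numeric",
                 sdDiscrepancy = "numeric", tauOpt = "numeric"),
  validity = function(object) {
    md <- object@meanDiscrepancy
    if (any(md[is.finite(md)] < 0)) return("discrepancies must be >= 0")
    best <- min(md[is.finite(md)])
    if (abs(md[match(object@tauOpt, object@thresholds)] - best) > 1e-12)
      return("tauOpt must attain the minimal mean discrepancy")
    TRUE
  })

#' Surface-variation (curvature) field
#'
#' Per-point surface variation delta_n = lambda0 / (lambda0+lambda1+lambda2)
#' of the local covariance eigenvalues (ascending); 0 for a perfectly planar
#' neighborhood, 1/3 for a perfectly isotropic one.
#'
#' @slot delta numeric per-point values in [0, 1/3]; NA where undefined.
#' @slot normals per-point normal estimates (eigenvector of the smallest
#'   eigenvalue), oriented consistently.
#' @slot radius spherical neighborhood radius, mm.
#' @slot defined logical: FALSE for points with fewer than 3 neighbors.
#' @export
setClass("CurvatureField",
  representation(delta = "numeric", normals = "matrix", radius = "numeric",
                 defined = "logical"),
  validity = function(object) {
    d <- object@delta[object@defined]
    if (length(d) && (min(d) < -1e-12 || max(d) > 1 / 3 + 1e-9))
      return("delta values must lie in [0, 1/3]")
    TRUE
  })

#' Margin line around one tooth
#'
#' A closed periodic cubic spline through ordered seed points, with
#' chord-length parameterization.
#'
#' @slot toothId ISO 3950 code.
#' @slot seeds K x 3 matrix of interpolation points, mm, in loop order.
#' @slot params chord-length parameter values of the seeds (first = 0).
#' @slot period total chord length (parameter period).
#' @export
setClass("MarginLine",
  representation(toothId = "character", seeds = "matrix", params = "numeric",
                 period = "numeric"))

#' Segmented mouth model
#'
#' @slot mesh combined crown + gingiva mouth mesh.
#' @slot assignment per-vertex label: a tooth id or "gingiva".
#' @slot margins list of MarginLine objects used for the split.
#' @export
setClass("SegmentedMouthModel",
  representation(mesh = "TriangleMesh", assignment = "character",
                 margins = "list"),
  validity = function(object) {
    if (length(object@assignment) != nrow(object@mesh@vertices))
      return("assignment must cover every vertex")
    TRUE
  })

#' Binary stripe pattern set for structured-light coding
#'
#' n temporally projected stripe patterns whose period halves at each step;
#' the code of a projector column is read MSB-first across the stack,
#' yielding l = 2^n - 1 encoded line boundaries.
#'
#' @slot n number of patterns (bits).
#' @slot patterns list of n binary matrices (rows = l_v, cols = l_h).
#' @slot lineCount encoded line count 2^n - 1.
#' @slot pointBudget encoded point budget l_h * l_v.
#' @slot stripePeriods stripe period (px) of each pattern.
#' @export
setClass("GrayCodePatternSet",
  representation(n = "integer", patterns = "list", lineCount = "numeric",
                 pointBudget = "numeric", stripePeriods = "numeric"),
  validity = function(object) {
    if (length(object@patterns) != object@n) return("need n patterns")
    if (object@lineCount != 2^object@n - 1)
      return("lineCount must equal 2^n - 1")
    TRUE
  })

#' Projector/camera rig geometry
#'
#' Camera pixel rays (origin + unit direction) and, per code value, the
#' projector light-plane equation n . x = d in mm.
#'
#' @slot rayOrigins P x 3 ray origins, mm.
#' @slot rayDirs P x 3 unit ray directions.
#' @slot imageDim c(rows, cols) of the camera image.
#' @slot planeNormals C x 3 unit plane normals (one per code).
#' @slot planeOffsets length-C plane offsets, mm.
#' @slot workingVolume 2 x 3 matrix (min row, max row), mm.
#' @export
setClass("ProjectorCameraRig",
  representation(rayOrigins = "matrix", rayDirs = "matrix",
                 imageDim = "integer", planeNormals = "matrix",
                 planeOffsets = "numeric", workingVolume = "matrix"),
  validity = function(object) {
    if (max(abs(sqrt(rowSums(object@rayDirs^2)) - 1)) > 1e-9)
      return("ray directions must be unit length")
    if (nrow(object@planeNormals) &&
        max(abs(sqrt(rowSums(object@planeNormals^2)) - 1)) > 1e-9)
      return("plane normals must be unit length")
    TRUE
  })

#' Decoded code map
#'
#' @slot codes integer matrix of per-pixel codes (0-based).
#' @slot valid logical matrix; FALSE where contrast was insufficient.
#' @slot n number of bits used for coding.
#' @export
setClass("CodeMap",
  representation(codes = "matrix", valid = "matrix", n = "integer"),
  validity = function(object) {
    cds <- object@codes[object@valid]
    if (length(cds) && (min(cds) < 0 || max(cds) > 2^object@n - 1))
      return("codes out of range [0, 2^n - 1]")
    TRUE
  })

#' Parametric tooth phantom specification
#'
#' Crown modeled as a superellipsoid (exponent 4), roots as tapered capsules
#' with a rounded apex; all cross sections perpendicular to the tooth axis
#' are closed-form, which provides the segmentation ground truth.
#'
#' @slot toothId ISO 3950 two-digit code (e.g. "11").
#' @slot crownHeight mm.
#' @slot crownRadii mm pair: superellipsoid semi-axes (a, b).
#' @slot rootCount 1, 2 or 3.
#' @slot rootLength mm.
#' @slot rootTaper fraction in (0, 1): radius reduction at the apex.
#' @slot pose rigid placement of the tooth local frame in world.
#' @export
setClass("ToothPhantomSpec",
  representation(toothId = "character", crownHeight = "numeric",
                 crownRadii = "numeric", rootCount = "integer",
                 rootLength = "numeric", rootTaper = "numeric",
                 pose = "RigidTransform"),
  validity = function(object) {
    if (!object@rootCount %in% 1:3) return("rootCount must be 1, 2 or 3")
    if (object@crownHeight <= 0 || object@rootLength <= 0 ||
        any(object@crownRadii <= 0))
      return("all lengths must be > 0")
    if (object@rootTaper <= 0 || object@rootTaper >= 1)
      return("rootTaper must be in (0, 1)")
    if (!isValidToothId(object@toothId))
      return(sprintf("'%s' is not a valid ISO 3950 tooth code", object@toothId))
    TRUE
  })

#' Jaw phantom
#'
#' Analytic multi-tooth phantom: per-tooth membership closures, crown and
#' gingiva meshes with ground-truth labels, bone/soft-tissue membership, and
#' the analytic helpers (cross-section area, volume) used as oracles.
#'
#' @slot specs list of ToothPhantomSpec.
#' @slot archParameters list (arch radius etc.), mm.
#' @slot gingivaMesh gingiva triangle mesh.
#' @slot crownMeshes list of per-tooth crown meshes (labels = tooth id).
#' @slot membership list of closures: \code{tooth[[i]](pts)},
#'   \code{bone(pts)}, \code{soft(pts)} returning logical.
#' @slot analytic list of closures: \code{crossSectionArea(i, z)},
#'   \code{toothVolume(i)}, \code{furcationZ(i)}, \code{boundaryRadius(i, z,
#'   theta)} in the tooth local frame.
#' @export
setClass("JawPhantom",
  representation(specs = "list", archParameters = "list",
                 gingivaMesh = "TriangleMesh", crownMeshes = "list",
                 membership = "list", analytic = "list"))

#' Tissue intensity model for phantom voxelization
#'
#' @slot huBackground,huSoftTissue,huBone,huTooth HU-like tissue intensities;
#'   must be strictly increasing in that order.
#' @slot noiseSd additive Gaussian noise SD, HU.
#' @slot streakAmplitude amplitude of simulated metal streak artifacts, HU
#'   (0 disables).
#' @slot seed integer seed for all randomness.
#' @export
setClass("IntensityModel",
  representation(huBackground = "numeric", huSoftTissue = "numeric",
                 huBone = "numeric", huTooth = "numeric", noiseSd = "numeric",
                 streakAmplitude = "numeric", seed = "integer"),
  validity = function(object) {
    if (!(object@huTooth > object@huBone &&
          object@huBone > object@huSoftTissue &&
          object@huSoftTissue > object@huBackground))
      return("tissue intensities must satisfy tooth > bone > soft > background")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })

#' Per-tooth assembly (crown + root + fused surface)
#'
#' @slot toothId ISO 3950 code.
#' @slot crownMesh optical crown mesh.
#' @slot rootMesh CBCT root mesh.
#' @slot fusedMesh fused mesh; contains every crown vertex verbatim.
#' @slot pose rigid pose applied to the whole tooth.
#' @export
setClass("ToothModel",
  representation(toothId = "character", crownMesh = "TriangleMesh",
                 rootMesh = "TriangleMesh", fusedMesh = "TriangleMesh",
                 pose = "RigidTransform"))

#' Multi-body orthodontic model
#'
#' Teeth, gingiva and socketed alveolar bone as independent bodies in one
#' common (CBCT) frame; each tooth carries its own rigid pose.
#'
#' @slot teeth list of ToothModel.
#' @slot gingiva gingiva mesh.
#' @slot bone socketed bone mesh.
#' @slot frame character tag naming the common frame.
#' @slot collisions data.frame of pairwise interpenetration flags.
#' @export
setClass("MultiBodyModel",
  representation(teeth = "list", gingiva = "TriangleMesh",
                 bone = "TriangleMesh", frame = "character",
                 collisions = "data.frame"))

#' Pipeline configuration
#'
#' Validated named parameter list driving \code{\link{runPipeline}}; unknown
#' keys are rejected and every run archives its resolved configuration next
#' to the outputs.
#'
#' @slot params named list of resolved parameters.
#' @export
setClass("PipelineConfig", representation(params = "list"))

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points%s%s\n", nrow(object@positions),
              if (!is.null(object@normals)) " (+normals)" else "",
              if (!is.null(object@labels)) " (+labels)" else ""))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x ")))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.3f deg, translation (%s) mm\n",
              ang, paste(format(object@translation, digits = 4),
                         collapse = ", ")))
})

setMethod("show", "ThresholdSweepResult", function(object) {
  cat(sprintf("ThresholdSweepResult: %d thresholds, tau_opt = %g HU\n",
              length(object@thresholds), object@tauOpt))
})

setMethod("show", "MultiBodyModel", function(object) {
  cat(sprintf("MultiBodyModel: %d teeth + gingiva + socketed bone [%s]\n",
              length(object@teeth), object@frame))
})
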