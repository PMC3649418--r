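# Pipeline driver: configuration, input validation and the end-to-end run
# (phantom -> scan merge -> crown segmentation -> CBCT alignment/threshold ->
# per-tooth DRLSE -> fusion).

.configDefaults <- function() list(
  seed = 1L,
  nTeeth = 2L,
  stages = c("phantom", "scan", "merge", "crowns", "cbct", "fuse"),
  viewCount = 6L,
  scanNoiseSd = 0.0,
  pointsPerView = 4000L,
  mergeTolerance = 0.05,
  curvatureRadius = 2.0,
  marginSeeds = 8L,
  voxelSpacing = 0.4,
  noiseSd = 20,
  streakAmplitude = 0,
  tauGrid = NULL,
  deltaEps = 1.0,
  drlse = list(mu = 0.2, lambda = 2, alpha = 0.5, sigma = 1.5,
               timeStep = 1, iterations = 150L, firstSliceIterations = 150L),
  seamBand = 0.5,
  outputDir = NULL)

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected; values override the documented defaults.
#' @param ... named parameters, or a single named list.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)))
    args <- args[[1]]
  defs <- .configDefaults()
  unknown <- setdiff(names(args), names(defs))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  new("PipelineConfig", params = utils::modifyList(defs, args))
}

#' Read a pipeline configuration from YAML or JSON
#' @param path configuration file.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  pipelineConfig(cfg)
}

#' Validate pipeline input files
#'
#' Reports (never mutates): mesh watertightness and unit sanity for STL
#' files (a bounding box beyond 1000 mm suggests meter-scaled data), DICOM
#' tag completeness for series directories.
#'
#' @param paths character vector of files/directories.
#' @return data.frame with columns path, check, status, message.
#' @export
validateInputs <- function(paths) {
  rows <- list()
  add <- function(path, check, status, message)
    rows[[length(rows) + 1L]] <<- data.frame(path = path, check = check,
                                             status = status,
                                             message = message)
  for (p in paths) {
    if (dir.exists(p)) {
      files <- list.files(p, pattern = "\\.dcm$", full.names = TRUE)
      if (!length(files)) {
        add(p, "dicom", "error", "no DICOM slices found")
        next
      }
      t1 <- tryCatch(.dcmReadFile(files[1]), error = function(e) NULL)
      if (is.null(t1)) {
        add(p, "dicom", "error", "unreadable DICOM file")
      } else {
        if (is.null(.dcmNumbers(t1, "00280030")))
          add(p, "dicom", "error", "missing PixelSpacing")
        else add(p, "dicom", "ok", "geometry tags present")
      }
    } else if (grepl("\\.stl$", p, ignore.case = TRUE)) {
      mesh <- tryCatch(readSTL(p), error = function(e) NULL)
      if (is.null(mesh)) {
        add(p, "stl", "error", "unreadable STL")
        next
      }
      ext <- apply(mesh@vertices, 2, function(v) diff(range(v)))
      if (max(ext) > 1000)
        add(p, "units", "warning",
            sprintf("bounding box %.0f mm: meters suspected", max(ext)))
      else add(p, "units", "ok", "plausible mm extents")
      open <- sum(meshEdges(mesh)$count == 1L)
      add(p, "watertight", if (open == 0L) "ok" else "warning",
          sprintf("%d boundary edges", open))
    } else {
      add(p, "exists", if (file.exists(p)) "ok" else "error",
          if (file.exists(p)) "file present" else "missing")
    }
  }
  do.call(rbind, rows)
}

#' Run the full multi-sensor pipeline on a synthetic phantom
#'
#' Executes the enabled stages in order: phantom generation, complementary
#' surface-scan simulation, ICP registration + merge, curvature-based crown
#' segmentation, CBCT voxelization + threshold-optimized alignment,
#' per-tooth DRLSE segmentation, bone segmentation with tooth subtraction,
#' and crown/root fusion into a multi-body model. Writes the resolved
#' configuration and a machine-readable report next to the outputs when an
#' output directory is configured.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return list: \code{model} (\linkS4class{MultiBodyModel} or NULL),
#'   \code{report} (named list of per-stage metrics), plus intermediate
#'   objects (\code{jaw}, \code{merged}, \code{segmentedMouth},
#'   \code{sweep}, \code{toothStacks}).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  p <- config@params
  stages <- p$stages
  report <- list(seed = p$seed)
  jaw <- merged <- segmented <- sweepRes <- NULL
  toothStacks <- list()
  teeth <- list()
  volume <- NULL

  if ("phantom" %in% stages) {
    jaw <- makeJawPhantom(defaultToothSpecs(p$nTeeth))
    report$phantom <- list(
      nTeeth = length(jaw@specs),
      toothVolumes = vapply(seq_along(jaw@specs), jaw@analytic$toothVolume,
                            numeric(1)))
  }

  if ("scan" %in% stages && !is.null(jaw)) {
    imp <- simulateSurfaceScan(jaw, "impression", viewCount = p$viewCount,
                               noiseSd = p$scanNoiseSd, seed = p$seed,
                               pointsPerView = p$pointsPerView)
    cast <- simulateSurfaceScan(jaw, "cast", viewCount = p$viewCount,
                                noiseSd = p$scanNoiseSd, seed = p$seed + 1L,
                                pointsPerView = p$pointsPerView)
    impCloud <- pointCloud(do.call(rbind, lapply(imp, positions)),
                           labels = unlist(lapply(imp, pointLabels)))
    castCloud <- pointCloud(do.call(rbind, lapply(cast, positions)),
                            labels = unlist(lapply(cast, pointLabels)))
    report$scan <- list(impressionPoints = nrow(impCloud@positions),
                        castPoints = nrow(castCloud@positions))
  }

  if ("merge" %in% stages && "scan" %in% stages && !is.null(jaw)) {
    # register on a subsample (sufficient for a rigid fit), merge in full
    set.seed(p$seed)
    si <- sample.int(nrow(impCloud@positions),
                     min(3000L, nrow(impCloud@positions)))
    ti <- sample.int(nrow(castCloud@positions),
                     min(3000L, nrow(castCloud@positions)))
    icp <- icpRegister(impCloud@positions[si, , drop = FALSE],
                       castCloud@positions[ti, , drop = FALSE],
                       maxIter = 15L, tol = 1e-6, rejectDist = 1.0)
    merged <- mergeScans(impCloud, castCloud, icp$transform,
                         mergeTolerance = p$mergeTolerance)
    report$merge <- list(rms = icp$rms, mergedPoints = nrow(merged@positions))
  }

  if ("crowns" %in% stages && !is.null(jaw)) {
    mouth <- mouthSurfaceMesh(jaw)
    curv <- surfaceVariation(mouth@vertices, radius = p$curvatureRadius)
    margins <- lapply(seq_along(jaw@specs), function(i)
      fitMarginSpline(marginSeedPoints(jaw, i, p$marginSeeds),
                      jaw@specs[[i]]@toothId))
    segmented <- segmentCrowns(mouth, curv, margins)
    agree <- mean(segmented@assignment == mouth@vertexLabels)
    report$crowns <- list(labelAgreement = agree)
  }

  if ("cbct" %in% stages && !is.null(jaw)) {
    im <- intensityModel(noiseSd = p$noiseSd,
                         streakAmplitude = p$streakAmplitude, seed = p$seed)
    volume <- voxelizePhantom(jaw, spacing = p$voxelSpacing, intensity = im)
    tauGrid <- p$tauGrid
    if (is.null(tauGrid))
      tauGrid <- seq(im@huSoftTissue + 100, im@huTooth - 100, by = 100)
    crown1 <- jaw@crownMeshes[[1]]
    lm <- list(source = crown1@vertices[c(1, 25, 50), , drop = FALSE],
               target = crown1@vertices[c(1, 25, 50), , drop = FALSE])
    sweepRes <- optimizeThreshold(crown1, volume, tauGrid, lm, p$deltaEps)
    report$cbct <- list(tauOpt = sweepRes@tauOpt,
                        meanDiscrepancy = min(sweepRes@meanDiscrepancy,
                                              na.rm = TRUE))
    params <- do.call(drlseParams, p$drlse)
    for (i in seq_along(jaw@specs)) {
      st <- segmentTooth(volume, jaw@crownMeshes[[i]], params,
                         toothId = jaw@specs[[i]]@toothId)
      toothStacks[[i]] <- st
    }
    vols <- vapply(toothStacks, function(s) sum(s@areas) * volume@spacing[3],
                   numeric(1))
    report$teeth <- list(segmentedVolumes = vols,
                         analyticVolumes = vapply(seq_along(jaw@specs),
                                                  jaw@analytic$toothVolume,
                                                  numeric(1)))
  }

  model <- NULL
  if ("fuse" %in% stages && length(toothStacks) && !is.null(segmented)) {
    for (i in seq_along(jaw@specs)) {
      id <- jaw@specs[[i]]@toothId
      crown <- crownSubMesh(segmented, id)
      root <- contoursToMesh(toothStacks[[i]])
      teeth[[i]] <- fuseCrownRoot(crown, root, p$seamBand, toothId = id)
    }
    model <- buildOrthodonticModel(teeth, jaw@gingivaMesh,
                                   frame = "cbct", checkCollisions = FALSE)
    report$fusion <- list(nTeeth = length(teeth))
  } else if (!is.null(segmented) && is.null(model) && !"cbct" %in% stages) {
    # CBCT stage disabled: crowns + gingiva only
    for (i in seq_along(jaw@specs)) {
      id <- jaw@specs[[i]]@toothId
      crown <- crownSubMesh(segmented, id)
      teeth[[i]] <- new("ToothModel", toothId = id, crownMesh = crown,
                        rootMesh = triangleMesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                        fusedMesh = crown, pose = rigidTransform())
    }
    model <- buildOrthodonticModel(teeth, jaw@gingivaMesh,
                                   frame = "optical", checkCollisions = FALSE)
  }

  if (!is.null(p$outputDir)) {
    dir.create(p$outputDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(p, file.path(p$outputDir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(report, file.path(p$outputDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(model)) exportModel(model, file.path(p$outputDir, "model"))
  }
  list(model = model, report = report, jaw = jaw,
       merged = merged, segmentedMouth = segmented, sweep = sweepRes,
       toothStacks = toothStacks, volume = volume)
}
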