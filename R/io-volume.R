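# CBCT-like volume I/O. A minimal CT DICOM series writer/reader (explicit VR
# little endian, single-frame slices) is implemented here; intensities are
# quantized to integer HU on write, as in real CT. A raw-array + JSON
# sidecar format is provided as the lighter-weight alternative.

.dcmExplicitLong <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcmElement <- function(group, elem, vr, value) {
  pad <- function(x, padByte = charToRaw(" ")) {
    b <- charToRaw(x)
    if (length(b) %% 2 == 1L) b <- c(b, padByte)
    b
  }
  body <- switch(vr,
    UI = pad(value, as.raw(0L)),
    DS = , IS = , CS = , LO = , SH = pad(as.character(value)),
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    OW = value,  # already raw
    stop("unhandled VR ", vr))
  hdr <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
           writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
           charToRaw(vr))
  if (vr %in% .dcmExplicitLong) {
    hdr <- c(hdr, raw(2),
             writeBin(as.integer(length(body)), raw(), size = 4,
                      endian = "little"))
  } else {
    hdr <- c(hdr, writeBin(as.integer(length(body)), raw(), size = 2,
                           endian = "little"))
  }
  c(hdr, body)
}

#' Write a voxel volume as a single-frame CT DICOM series
#'
#' One explicit-VR little-endian file per slice with the standard CT geometry
#' tags (PixelSpacing, SliceThickness, ImagePositionPatient,
#' ImageOrientationPatient, RescaleSlope/Intercept). Intensities are rounded
#' to integer HU (16-bit signed).
#'
#' @param volume a \linkS4class{VoxelVolume}.
#' @param dir output directory (created if needed).
#' @param seriesPrefix file-name prefix.
#' @return invisibly, the written file paths.
#' @export
writeDicomSeries <- function(volume, dir, seriesPrefix = "slice") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- volume@intensities
  d <- dim(a); sp <- volume@spacing; org <- volume@origin
  uidBase <- "1.2.826.0.1.3680043.9999"
  paths <- character(d[3])
  for (iz in seq_len(d[3])) {
    slice <- round(a[, , iz])
    stopifnot(max(abs(slice)) < 32768)
    # PixelData row-major with rows = y, columns = x: for each row (y) all x
    # values, which is exactly R's column-major order for slice[x, y]
    pix <- writeBin(as.integer(as.vector(slice)), raw(), size = 2,
                    endian = "little")
    sopUid <- sprintf("%s.%d.%d", uidBase, as.integer(Sys.getpid()) %% 1000L, iz)
    meta <- c(.dcmElement(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.2"),
              .dcmElement(0x0002, 0x0003, "UI", sopUid),
              .dcmElement(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
    metaLenBody <- writeBin(as.integer(length(meta)), raw(), size = 4,
                            endian = "little")
    metaLen <- c(writeBin(as.integer(0x0002), raw(), size = 2, endian = "little"),
                 writeBin(as.integer(0x0000), raw(), size = 2, endian = "little"),
                 charToRaw("UL"),
                 writeBin(4L, raw(), size = 2, endian = "little"),
                 metaLenBody)
    ipp <- sprintf("%.10g\\%.10g\\%.10g", org[1], org[2], org[3] + (iz - 1) * sp[3])
    ds <- c(
      .dcmElement(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.2"),
      .dcmElement(0x0008, 0x0018, "UI", sopUid),
      .dcmElement(0x0018, 0x0050, "DS", sprintf("%.10g", sp[3])),
      .dcmElement(0x0020, 0x0013, "IS", as.character(iz)),
      .dcmElement(0x0020, 0x0032, "DS", ipp),
      .dcmElement(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      .dcmElement(0x0028, 0x0002, "US", 1L),
      .dcmElement(0x0028, 0x0010, "US", d[2]),   # Rows = y count
      .dcmElement(0x0028, 0x0011, "US", d[1]),   # Columns = x count
      .dcmElement(0x0028, 0x0030, "DS", sprintf("%.10g\\%.10g", sp[2], sp[1])),
      .dcmElement(0x0028, 0x0100, "US", 16L),
      .dcmElement(0x0028, 0x0101, "US", 16L),
      .dcmElement(0x0028, 0x0102, "US", 15L),
      .dcmElement(0x0028, 0x0103, "US", 1L),
      .dcmElement(0x0028, 0x1052, "DS", "0"),
      .dcmElement(0x0028, 0x1053, "DS", "1"),
      .dcmElement(0x7FE0, 0x0010, "OW", pix))
    paths[iz] <- file.path(dir, sprintf("%s_%04d.dcm", seriesPrefix, iz))
    con <- file(paths[iz], "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(metaLen, meta, ds), con)
    close(con)
  }
  invisible(paths)
}

.dcmReadFile <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  u16 <- function(at) sum(as.integer(raw[at:(at + 1)]) * c(1, 256))
  u32 <- function(at) sum(as.integer(raw[at:(at + 3)]) * c(1, 256, 65536, 16777216))
  tags <- list()
  while (pos + 7L <= length(raw)) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .dcmExplicitLong) {
      len <- u32(pos + 8L); valAt <- pos + 12L
    } else {
      len <- u16(pos + 6L); valAt <- pos + 8L
    }
    val <- raw[valAt:(valAt + len - 1L)]
    key <- sprintf("%04x%04x", grp, ele)
    tags[[key]] <- list(vr = vr, value = val)
    pos <- valAt + len
    if (grp == 0x7FE0 && ele == 0x0010) break
  }
  tags
}

.dcmString <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$value[el$value != as.raw(0L)]))
}

.dcmNumbers <- function(tags, key) {
  s <- .dcmString(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcmUint16 <- function(tags, key) {
  el <- tags[[key]]
  if (is.null(el)) return(NULL)
  sum(as.integer(el$value[1:2]) * c(1L, 256L))
}

#' Load a DICOM series as a voxel volume
#'
#' Reads a directory of single-frame explicit-VR little-endian slices,
#' sorts them by position along the slice normal (file order is ignored),
#' applies RescaleSlope/Intercept and populates spacing and origin.
#'
#' @param path directory containing .dcm files.
#' @return a \linkS4class{VoxelVolume}.
#' @export
loadDicomSeries <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM files found in ", path)
  parsed <- lapply(files, .dcmReadFile)
  orients <- vapply(parsed, function(t)
    paste(.dcmNumbers(t, "00200037"), collapse = ","), character(1))
  if (length(unique(orients)) != 1L)
    stop("format error: slices have inconsistent orientation")
  ps <- .dcmNumbers(parsed[[1]], "00280030")
  if (is.null(ps)) stop("format error: missing PixelSpacing")
  thick <- .dcmNumbers(parsed[[1]], "00180050")
  pos <- t(vapply(parsed, function(t) .dcmNumbers(t, "00200032"), numeric(3)))
  ord <- order(pos[, 3])
  parsed <- parsed[ord]; pos <- pos[ord, , drop = FALSE]
  rows <- .dcmUint16(parsed[[1]], "00280010")
  cols <- .dcmUint16(parsed[[1]], "00280011")
  nz <- length(parsed)
  dz <- if (nz > 1) stats::median(diff(pos[, 3])) else thick
  a <- array(0, c(cols, rows, nz))
  for (iz in seq_len(nz)) {
    t_ <- parsed[[iz]]
    slope <- .dcmNumbers(t_, "00281053"); icept <- .dcmNumbers(t_, "00281052")
    if (is.null(slope)) slope <- 1
    if (is.null(icept)) icept <- 0
    pix <- readBin(t_[["7fe00010"]]$value, "integer", n = rows * cols,
                   size = 2, endian = "little", signed = TRUE)
    a[, , iz] <- matrix(pix, nrow = cols, ncol = rows)[, ] * slope + icept
  }
  new("VoxelVolume", intensities = a, spacing = c(ps[2], ps[1], dz),
      origin = pos[1, ], labels = NULL)
}

#' Write a voxel volume as raw array + JSON metadata sidecar
#' @param volume a \linkS4class{VoxelVolume}.
#' @param prefix path prefix; writes \code{<prefix>.raw} and
#'   \code{<prefix>.json}.
#' @export
writeRawVolume <- function(volume, prefix) {
  con <- file(paste0(prefix, ".raw"), "wb")
  writeBin(as.vector(volume@intensities), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(list(dims = dim(volume@intensities),
                            spacing = volume@spacing, origin = volume@origin),
                       paste0(prefix, ".json"), digits = NA, auto_unbox = FALSE)
  invisible(prefix)
}

#' Read a raw + JSON sidecar volume
#' @param prefix path prefix used by \code{\link{writeRawVolume}}.
#' @export
readRawVolume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(paste0(prefix, ".raw"), "rb")
  a <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  new("VoxelVolume", intensities = array(a, meta$dims),
      spacing = meta$spacing, origin = meta$origin, labels = NULL)
}
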