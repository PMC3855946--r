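# Volume and image I/O.
#
# NIfTI goes through RNifti. MetaImage (.mhd/.mha) and the raw+sidecar format
# are implemented here: the header is a small key = value text block and the
# payload is a plain binary dump, so no external dependency is needed.

.metaTypeMap <- c(MET_UCHAR = "uint8", MET_CHAR = "int8", MET_SHORT = "int16",
                  MET_USHORT = "uint16", MET_INT = "int32",
                  MET_FLOAT = "float32", MET_DOUBLE = "float64")

.dtypeBytes <- c(uint8 = 1L, int8 = 1L, int16 = 2L, uint16 = 2L, int32 = 4L,
                 float32 = 4L, float64 = 8L)

.readPayload <- function(con, n, dtype, endian) {
  switch(dtype,
    uint8   = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    int8    = as.numeric(readBin(con, "integer", n, size = 1L, signed = TRUE)),
    int16   = as.numeric(readBin(con, "integer", n, size = 2L, signed = TRUE,
                                 endian = endian)),
    uint16  = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                                 endian = endian)),
    int32   = as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
    float32 = readBin(con, "double", n, size = 4L, endian = endian),
    float64 = readBin(con, "double", n, size = 8L, endian = endian),
    stop("unsupported dtype: ", dtype))
}

.writePayload <- function(x, con, dtype, endian) {
  if (dtype %in% c("uint8", "int8", "int16", "uint16", "int32")) {
    writeBin(as.integer(round(x)), con, size = .dtypeBytes[[dtype]],
             endian = endian)
  } else {
    writeBin(as.numeric(x), con, size = .dtypeBytes[[dtype]], endian = endian)
  }
}

.parseKeyValues <- function(lines, sep = "=") {
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexpr(sep, lines, fixed = TRUE), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", ""))
  stats::setNames(as.list(vals), keys)
}

.numFields <- function(s) as.numeric(strsplit(trimws(s), "[ ,]+")[[1]])

.checkVolumeFinite <- function(data, path) {
  if (anyNA(data))
    stop("volume '", path, "' contains undefined (NaN/NA) voxel values")
  invisible(TRUE)
}

.readMeta <- function(path) {
  # .mha keeps the payload in the same file after "ElementDataFile = LOCAL";
  # .mhd points at a separate raw file.
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) break
    header <- c(header, line)
    if (grepl("^\\s*ElementDataFile", line)) break
  }
  kv <- .parseKeyValues(header)
  need <- c("DimSize", "ElementType", "ElementDataFile")
  missing <- setdiff(need, names(kv))
  if (length(missing))
    stop("MetaImage header of '", path, "' lacks key(s): ",
         paste(missing, collapse = ", "))
  dims <- as.integer(.numFields(kv$DimSize))
  if (length(dims) != 3L)
    stop("MetaImage '", path, "' is not a 3D volume")
  dtype <- .metaTypeMap[[kv$ElementType]]
  if (is.null(dtype)) stop("unsupported ElementType: ", kv$ElementType)
  spacing <- if (!is.null(kv$ElementSpacing)) .numFields(kv$ElementSpacing)
             else c(1, 1, 1)
  orig <- if (!is.null(kv$Offset)) .numFields(kv$Offset) else c(0, 0, 0)
  endian <- if (identical(kv$ElementByteOrderMSB, "True")) "big" else "little"
  n <- prod(dims)
  if (identical(kv$ElementDataFile, "LOCAL")) {
    vals <- .readPayload(con, n, dtype, endian)
  } else {
    rawPath <- file.path(dirname(path), kv$ElementDataFile)
    if (!file.exists(rawPath))
      stop("cannot read MetaImage payload '", rawPath, "'")
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- .readPayload(rcon, n, dtype, endian)
  }
  if (length(vals) != n)
    stop("MetaImage '", path, "': payload has ", length(vals),
         " values, header declares ", n)
  tag <- if (identical(kv$Modality, "MET_MOD_CT")) "HU" else "raw"
  .checkVolumeFinite(vals, path)
  CTVolume(array(vals, dims), spacing = spacing, origin = orig, unitTag = tag)
}

.writeMeta <- function(volume, path, dtype = "float64") {
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  dataFile <- if (local) "LOCAL"
              else paste0(sub("\\.mhd$", "", basename(path)), ".raw")
  metaType <- names(.metaTypeMap)[match(dtype, .metaTypeMap)]
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "ElementByteOrderMSB = False",
    "CompressedData = False",
    paste("DimSize =", paste(dim(volume@data), collapse = " ")),
    paste("ElementSpacing =", paste(volume@spacing, collapse = " ")),
    paste("Offset =", paste(volume@origin, collapse = " ")),
    if (volume@unitTag == "HU") "Modality = MET_MOD_CT",
    paste("ElementType =", metaType),
    paste("ElementDataFile =", dataFile))
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(header, con)
  if (local) {
    .writePayload(volume@data, con, dtype, "little")
  } else {
    rcon <- file(file.path(dirname(path), dataFile), "wb")
    on.exit(close(rcon), add = TRUE)
    .writePayload(volume@data, rcon, dtype, "little")
  }
  invisible(path)
}

.sidecarPath <- function(path) {
  cand <- c(paste0(path, ".meta"), paste0(sub("\\.[^.]+$", "", path), ".meta"))
  hit <- cand[file.exists(cand)]
  if (length(hit) == 0L)
    stop("no sidecar metadata found for raw volume '", path,
         "' (expected ", cand[1L], ")")
  hit[1L]
}

.readRaw <- function(path) {
  kv <- .parseKeyValues(readLines(.sidecarPath(path), warn = FALSE))
  for (key in c("dims", "dtype"))
    if (is.null(kv[[key]]))
      stop("raw sidecar for '", path, "' lacks required key '", key, "'")
  dims <- as.integer(.numFields(kv$dims))
  if (length(dims) != 3L || any(is.na(dims)))
    stop("raw sidecar for '", path, "': dims must be three integers")
  dtype <- kv$dtype
  if (!dtype %in% names(.dtypeBytes))
    stop("raw sidecar for '", path, "': unsupported dtype '", dtype, "'")
  endian <- if (identical(kv$endianness, "big")) "big" else "little"
  expected <- prod(dims) * .dtypeBytes[[dtype]]
  if (file.info(path)$size != expected)
    stop("raw volume '", path, "': file has ", file.info(path)$size,
         " bytes but dims x dtype require ", expected)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- .readPayload(con, prod(dims), dtype, endian)
  spacing <- if (!is.null(kv$spacing)) .numFields(kv$spacing) else c(1, 1, 1)
  orig <- if (!is.null(kv$origin)) .numFields(kv$origin) else c(0, 0, 0)
  tag <- if (identical(kv$units, "HU")) "HU" else "raw"
  .checkVolumeFinite(vals, path)
  CTVolume(array(vals, dims), spacing = spacing, origin = orig, unitTag = tag)
}

.writeRaw <- function(volume, path, dtype = "float64") {
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e)))
  .writePayload(volume@data, con, dtype, "little")
  close(con)
  sidecar <- c(
    paste0("dims=", paste(dim(volume@data), collapse = ",")),
    paste0("spacing=", paste(volume@spacing, collapse = ",")),
    paste0("origin=", paste(volume@origin, collapse = ",")),
    paste0("dtype=", dtype),
    "endianness=little",
    if (volume@unitTag == "HU") "units=HU")
  writeLines(sidecar, paste0(path, ".meta"))
  invisible(path)
}

.readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (length(dim(img)) != 3L)
    stop("NIfTI volume '", path, "' is not 3D")
  data <- array(as.numeric(img), dim(img))
  sp <- abs(hdr$pixdim[2:4])
  sp[sp == 0] <- 1
  aff <- try(RNifti::xform(img), silent = TRUE)
  orig <- if (inherits(aff, "try-error")) c(0, 0, 0) else as.numeric(aff[1:3, 4])
  tag <- if (grepl("HU|Hounsfield", hdr$descrip %||% "", ignore.case = TRUE))
    "HU" else "raw"
  .checkVolumeFinite(data, path)
  CTVolume(data, spacing = sp, origin = orig, unitTag = tag)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

.writeNiftiVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@data)
  img <- RNifti::asNifti(img, list(
    pixdim = c(1, volume@spacing, rep(0, 4)),
    qoffset_x = volume@origin[1], qoffset_y = volume@origin[2],
    qoffset_z = volume@origin[3], qform_code = 1L,
    descrip = if (volume@unitTag == "HU") "HU" else volume@unitTag))
  RNifti::writeNifti(img, path)
  invisible(path)
}

.detectFormat <- function(path, formatHint = NULL) {
  if (!is.null(formatHint)) {
    hint <- tolower(formatHint)
    if (hint %in% c("nifti", "nii")) return("nifti")
    if (hint %in% c("metaimage", "mhd", "mha", "meta")) return("meta")
    if (hint %in% c("raw")) return("raw")
    stop("unknown format hint: ", formatHint)
  }
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mhd|mha)$", low)) return("meta")
  if (grepl("\\.raw$", low)) return("raw")
  stop("cannot infer volume format from '", path,
       "'; pass formatHint = 'nifti', 'metaimage' or 'raw'")
}

#' Read a CT volume
#'
#' Reads NIfTI-1 (.nii/.nii.gz), MetaImage (.mhd/.mha) or headerless raw
#' volumes with a key=value sidecar (<path>.meta giving dims, spacing, dtype,
#' endianness and optionally origin and units). The unit tag is set to
#' \code{"HU"} when the header declares Hounsfield scaling (NIfTI description
#' containing "HU", MetaImage \code{Modality = MET_MOD_CT}, sidecar
#' \code{units=HU}) and \code{"raw"} otherwise. Volumes containing undefined
#' values are rejected with a diagnostic.
#'
#' @param path path to the volume file.
#' @param formatHint optional format name overriding extension-based
#'   detection (\code{"nifti"}, \code{"metaimage"}, \code{"raw"}).
#' @return A \linkS4class{CTVolume}.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path, formatHint = NULL) {
  if (!file.exists(path)) stop("cannot read volume: '", path, "' does not exist")
  switch(.detectFormat(path, formatHint),
         nifti = .readNiftiVolume(path),
         meta = .readMeta(path),
         raw = .readRaw(path))
}

#' Write a CT volume
#'
#' Writes the format implied by the file extension (.nii/.nii.gz, .mhd/.mha,
#' .raw+sidecar). Data are stored as 64-bit floats for MetaImage and raw so
#' that \code{readVolume(writeVolume(v))} round-trips bitwise.
#'
#' @param volume a \linkS4class{CTVolume}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  validObject(volume)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write '", path, "': directory missing")
  if (file.access(dir, 2L) != 0L)
    stop("cannot write '", path, "': directory not writable")
  switch(.detectFormat(path),
         nifti = .writeNiftiVolume(volume, path),
         meta = .writeMeta(volume, path),
         raw = .writeRaw(volume, path))
  invisible(path)
}

#' Write an 8-bit ultrasound image
#'
#' Writes a lossless 8-bit grayscale PNG or binary PGM (P5); masked-out
#' pixels are written as 0 (they already are 0 by the class invariant).
#'
#' @param image an \linkS4class{UltrasoundImage}, or an integer matrix in
#'   [0, 255].
#' @param path output path ending in .png or .pgm.
#' @return The path, invisibly.
#' @export
writeImage <- function(image, path) {
  px <- if (is(image, "UltrasoundImage")) {
    validObject(image)
    image@pixels
  } else image
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("image pixels must lie in [0, 255]")
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop("cannot write image '", path, "': directory missing or not writable")
  low <- tolower(path)
  if (grepl("\\.png$", low)) {
    png::writePNG(px / 255, path)
  } else if (grepl("\\.pgm$", low)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(px), nrow(px)), con,
              eos = NULL)
    writeBin(as.integer(round(t(px))), con, size = 1L)
  } else stop("unsupported image format for '", path, "' (use .png or .pgm)")
  invisible(path)
}

#' Read an 8-bit grayscale image written by writeImage
#'
#' @param path path to a .png or .pgm file.
#' @return Integer matrix of pixel values in [0, 255].
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: '", path, "' missing")
  low <- tolower(path)
  if (grepl("\\.png$", low)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    return(matrix(as.integer(round(px * 255)), nrow(px), ncol(px)))
  }
  if (grepl("\\.pgm$", low)) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readLines(con, n = 1L)
    if (!identical(magic, "P5")) stop("'", path, "' is not a binary PGM")
    dims <- .numFields(readLines(con, n = 1L))
    maxv <- as.integer(readLines(con, n = 1L))
    vals <- readBin(con, "integer", prod(dims), size = 1L, signed = FALSE)
    return(t(matrix(as.integer(vals), dims[1L], dims[2L])))
  }
  stop("unsupported image format for '", path, "'")
}
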