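# ENVI-style band-sequential cube I/O.
#
# A cube <path> is stored as three files:
#   <path>          raw BSQ binary (uint16 for DN cubes, float32 for
#                   reflectance cubes), little endian, row-major per band
#   <path>.hdr      ENVI text header (samples/lines/bands/data type/
#                   interleave/byte order/wavelength)
#   <path>.meta.json sidecar with bit depth, per-band exposure, grid
#                   convention and artefact flags (information the ENVI
#                   header has no standard fields for)

.enviHeader <- function(nrow, ncol, nb, dataType, wl) {
  c("ENVI",
    "description = {hscolpo band-sequential cube}",
    paste0("samples = ", ncol),
    paste0("lines = ", nrow),
    paste0("bands = ", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", dataType),
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(wl, trim = TRUE), collapse = ", "), "}"))
}

.parseEnviHeader <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fields <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (grepl("=", line, fixed = TRUE)) {
      key <- tolower(trimws(sub("=.*", "", line)))
      val <- trimws(sub("^[^=]*=", "", line))
      # a {...} list may span several lines
      while (grepl("{", val, fixed = TRUE) && !grepl("}", val, fixed = TRUE) &&
             i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[i]))
      }
      fields[[key]] <- val
    }
    i <- i + 1L
  }
  fields
}

.parseEnviList <- function(x) {
  x <- gsub("[{}]", "", x)
  as.numeric(trimws(strsplit(x, ",")[[1]]))
}

#' Write a cube to an ENVI-style band-sequential file set
#'
#' Raw [HSCube-class] data are written as unsigned 16-bit integers
#' (ENVI data type 12), [ReflectanceCube-class] data as 32-bit floats
#' (data type 4, so reflectance round trips at single precision). A text
#' `.hdr` header carries geometry and wavelengths; a `.meta.json` sidecar
#' carries bit depth, per-band exposure, grid convention, artefact flags
#' and (for reflectance cubes) the invalid-voxel sentinel.
#'
#' @param cube an [HSCube-class] or [ReflectanceCube-class].
#' @param path data-file path; `<path>.hdr` and `<path>.meta.json` are
#'   written next to it.
#' @return `path`, invisibly.
#' @seealso [readCube()]
#' @export
writeCube <- function(cube, path) {
  d <- dim(cube@data)
  isRaw <- is(cube, "HSCube")
  dataType <- if (isRaw) 12L else 4L
  writeLines(.enviHeader(d[1], d[2], d[3], dataType, wavelengths(cube)),
             paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  sentinel <- -999
  for (b in seq_len(d[3])) {
    plane <- cube@data[, , b]
    if (!isRaw && any(cube@invalidMask[, , b]))
      plane[cube@invalidMask[, , b]] <- sentinel
    v <- as.vector(t(plane))  # ENVI is row-major within a band
    if (isRaw) writeBin(as.integer(v), con, size = 2L, endian = "little")
    else writeBin(as.numeric(v), con, size = 4L, endian = "little")
  }
  g <- cube@grid
  meta <- list(
    class = if (isRaw) "HSCube" else "ReflectanceCube",
    grid = list(startNm = g@startNm, endNm = g@endNm, stepNm = g@stepNm,
                convention = g@convention),
    bitDepth = if (isRaw) cube@bitDepth else NULL,
    exposureMs = if (isRaw) cube@exposureMs else NULL,
    artefactBands = if (isRaw) cube@artefactBands else NULL,
    invalidSentinel = if (isRaw) NULL else sentinel)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cube written by [writeCube()]
#'
#' Validates the header against the binary payload: a wavelength list whose
#' length differs from the declared band count, an unknown interleave, an
#' unsupported data type or a file-size mismatch all raise errors. Raw DN
#' cubes round trip bit-exactly.
#'
#' @param path data-file path (as passed to [writeCube()]).
#' @return an [HSCube-class] or [ReflectanceCube-class].
#' @export
readCube <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(path)) stop("no such cube file: ", path)
  if (!file.exists(hdrPath)) stop("missing ENVI header: ", hdrPath)
  h <- .parseEnviHeader(hdrPath)
  nrow <- as.integer(h[["lines"]]); ncol <- as.integer(h[["samples"]])
  nb <- as.integer(h[["bands"]]); dataType <- as.integer(h[["data type"]])
  interleave <- tolower(h[["interleave"]])
  if (!identical(interleave, "bsq"))
    stop("unknown interleave '", interleave, "' (only bsq is supported)")
  if (!dataType %in% c(4L, 12L))
    stop("unsupported ENVI data type ", dataType)
  wl <- .parseEnviList(h[["wavelength"]])
  if (length(wl) != nb)
    stop(sprintf("header wavelength count (%d) does not match band count (%d)",
                 length(wl), nb))
  bytes <- if (dataType == 12L) 2L else 4L
  expectBytes <- as.numeric(nrow) * ncol * nb * bytes
  if (file.info(path)$size != expectBytes)
    stop(sprintf("file size %d does not match %d x %d x %d cube (%g bytes)",
                 file.info(path)$size, nrow, ncol, nb, expectBytes))
  metaPath <- paste0(path, ".meta.json")
  if (!file.exists(metaPath)) stop("missing sidecar metadata: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  grid <- makeGrid(meta$grid$startNm, meta$grid$endNm, meta$grid$stepNm,
                   meta$grid$convention)
  if (length(wavelengths(grid)) != nb ||
      any(abs(wavelengths(grid) - wl) > 1e-4))
    stop("sidecar grid does not reproduce the header wavelength list")
  con <- file(path, "rb")
  on.exit(close(con))
  arr <- array(if (dataType == 12L) 0L else 0, dim = c(nrow, ncol, nb))
  for (b in seq_len(nb)) {
    v <- if (dataType == 12L)
      readBin(con, "integer", n = nrow * ncol, size = 2L, signed = FALSE,
              endian = "little")
    else readBin(con, "numeric", n = nrow * ncol, size = 4L, endian = "little")
    arr[, , b] <- t(matrix(v, nrow = ncol, ncol = nrow))
  }
  if (dataType == 12L) {
    .newHSCube(arr, grid, as.integer(meta$bitDepth),
               as.numeric(meta$exposureMs),
               as.integer(meta$artefactBands %||% integer()))
  } else {
    sentinel <- meta$invalidSentinel %||% -999
    invalid <- arr <= sentinel + 0.5
    arr[invalid] <- 0
    new("ReflectanceCube", data = arr, grid = grid, invalidMask = invalid)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
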