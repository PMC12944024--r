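#' Construct an equally spaced wavelength grid
#'
#' Builds a [SpectralGrid-class] from a span, a step and an endpoint
#' convention. `"closed"` includes both endpoints as band centers
#' (`(end - start)/step + 1` bands); `"half_open"` excludes the upper
#' endpoint (`(end - start)/step` bands).
#'
#' @param startNm,endNm span in nm, `startNm < endNm`.
#' @param stepNm band spacing in nm, > 0; the span must be divisible by it.
#' @param convention `"closed"` (default) or `"half_open"`.
#' @return a [SpectralGrid-class].
#' @examples
#' nBands(makeGrid(460, 1000, 5))               # 109
#' nBands(makeGrid(650, 1100, 5, "half_open"))  # 90
#' @export
makeGrid <- function(startNm, endNm, stepNm, convention = c("closed", "half_open")) {
  convention <- match.arg(convention)
  if (stepNm <= 0) stop("stepNm must be > 0, got ", stepNm)
  if (startNm >= endNm) stop("startNm must be < endNm")
  span <- endNm - startNm
  k <- span / stepNm
  rem <- abs(k - round(k))
  if (rem > 1e-8)
    stop(sprintf("span %g nm is not divisible by step %g nm (remainder %g nm)",
                 span, stepNm, span - floor(k) * stepNm))
  n <- round(k)
  wl <- startNm + stepNm * (0:n)
  if (convention == "half_open") wl <- wl[-length(wl)]
  new("SpectralGrid", startNm = startNm, endNm = endNm, stepNm = stepNm,
      convention = convention, wavelengths = wl)
}

#' Construct a unit-tagged Spectrum
#'
#' @param grid a [SpectralGrid-class].
#' @param values one value per band.
#' @param unit one of `"reflectance"`, `"dn"`, `"db"`, `"ms"`, `"ratio"`,
#'   `"arbitrary"`.
#' @return a [Spectrum-class].
#' @export
makeSpectrum <- function(grid, values, unit = "reflectance") {
  new("Spectrum", grid = grid, values = as.numeric(values), unit = unit)
}

#' Flag reflectance values overshooting 1
#'
#' Calibrated reflectance can exceed 1 slightly from noise; values are
#' retained (so error statistics stay unbiased) and this helper flags them.
#'
#' @param x a reflectance-tagged [Spectrum-class].
#' @param epsilon overshoot tolerance (default 0).
#' @return logical vector, TRUE where `values > 1 + epsilon`.
#' @export
reflectanceOvershoot <- function(x, epsilon = 0) {
  stopifnot(is(x, "Spectrum"))
  x@values > 1 + epsilon
}

#' @describeIn wavelengths band centers of a grid
#' @export
setMethod("wavelengths", "SpectralGrid", function(x) x@wavelengths)
#' @describeIn wavelengths band centers of a spectrum's grid
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@grid@wavelengths)
#' @describeIn wavelengths band centers of a cube
#' @export
setMethod("wavelengths", "HSCube", function(x) x@grid@wavelengths)
#' @describeIn wavelengths band centers of a calibrated cube
#' @export
setMethod("wavelengths", "ReflectanceCube", function(x) x@grid@wavelengths)
#' @describeIn wavelengths band centers of an exposure profile
#' @export
setMethod("wavelengths", "ExposureProfile", function(x) x@grid@wavelengths)
#' @describeIn wavelengths band centers of a scene target
#' @export
setMethod("wavelengths", "SceneTarget", function(x) x@grid@wavelengths)

#' @describeIn nBands band count of a grid
#' @export
setMethod("nBands", "SpectralGrid", function(x) length(x@wavelengths))
#' @describeIn nBands band count of a spectrum
#' @export
setMethod("nBands", "Spectrum", function(x) length(x@grid@wavelengths))
#' @describeIn nBands band count of a cube
#' @export
setMethod("nBands", "HSCube", function(x) length(x@grid@wavelengths))
#' @describeIn nBands band count of a calibrated cube
#' @export
setMethod("nBands", "ReflectanceCube", function(x) length(x@grid@wavelengths))
#' @describeIn nBands band count of an exposure profile
#' @export
setMethod("nBands", "ExposureProfile", function(x) length(x@grid@wavelengths))

#' @describeIn spectrumValues values of a spectrum
#' @export
setMethod("spectrumValues", "Spectrum", function(x) x@values)
#' @describeIn spectrumUnit unit of a spectrum
#' @export
setMethod("spectrumUnit", "Spectrum", function(x) x@unit)

#' @describeIn cubeData DN array of a raw cube
#' @export
setMethod("cubeData", "HSCube", function(x) x@data)
#' @describeIn cubeData reflectance array of a calibrated cube
#' @export
setMethod("cubeData", "ReflectanceCube", function(x) x@data)

#' @describeIn bitDepth bit depth of a raw cube
#' @export
setMethod("bitDepth", "HSCube", function(x) x@bitDepth)
#' @describeIn exposureTimes per-band exposures of a raw cube
#' @export
setMethod("exposureTimes", "HSCube", function(x) x@exposureMs)
#' @describeIn exposureTimes per-band exposures of a profile
#' @export
setMethod("exposureTimes", "ExposureProfile", function(x) x@tMs)
#' @describeIn saturatedMask saturation mask of a raw cube
#' @export
setMethod("saturatedMask", "HSCube", function(x) x@saturated)
#' @describeIn invalidMask invalid mask of a calibrated cube
#' @export
setMethod("invalidMask", "ReflectanceCube", function(x) x@invalidMask)
#' @describeIn artefactBands flagged bands of a raw cube
#' @export
setMethod("artefactBands", "HSCube", function(x) x@artefactBands)
#' @describeIn lowSensitivityBands capped-band flags of a profile
#' @export
setMethod("lowSensitivityBands", "ExposureProfile", function(x) x@lowSensitivity)

# internal constructor: DN array -> HSCube with consistent saturation mask
.newHSCube <- function(data, grid, bitDepth, exposureMs,
                       artefactBands = integer()) {
  maxDn <- 2^bitDepth - 1
  storage.mode(data) <- "integer"
  new("HSCube", data = data, grid = grid, bitDepth = as.integer(bitDepth),
      exposureMs = as.numeric(exposureMs), saturated = data == maxDn,
      artefactBands = as.integer(artefactBands))
}

#' Construct a square region of interest
#'
#' @param centerRow,centerCol center pixel (1-based).
#' @param size side length in pixels.
#' @return a [RegionOfInterest-class].
#' @export
makeRoi <- function(centerRow, centerCol, size) {
  new("RegionOfInterest", centerRow = as.integer(centerRow),
      centerCol = as.integer(centerCol), size = as.integer(size))
}

.roiRows <- function(roi) {
  r0 <- roi@centerRow - (roi@size - 1L) %/% 2L
  r0:(r0 + roi@size - 1L)
}
.roiCols <- function(roi) {
  c0 <- roi@centerCol - (roi@size - 1L) %/% 2L
  c0:(c0 + roi@size - 1L)
}

#' Mean and standard-deviation spectrum over a square region
#'
#' Computes, per band, the mean and the population standard deviation
#' (divide by n) of the voxels inside the region, together with the number
#' of saturated voxels per band (for raw cubes).
#'
#' @param cube an [HSCube-class] or [ReflectanceCube-class].
#' @param roi a [RegionOfInterest-class]; must lie fully inside the image.
#' @return list with elements `mean` and `sd` ([Spectrum-class]) and
#'   `nSaturated` (integer per band; all zero for reflectance cubes).
#' @examples
#' g <- makeGrid(500, 520, 10)
#' cube <- hscolpo:::.newHSCube(array(100L, c(4, 4, 3)), g, 10, rep(1, 3))
#' s <- extractRoiSpectrum(cube, makeRoi(2, 2, 2))
#' spectrumValues(s$mean)  # 100 100 100
#' @export
extractRoiSpectrum <- function(cube, roi) {
  stopifnot(is(cube, "HSCube") || is(cube, "ReflectanceCube"))
  d <- dim(cube@data)
  rows <- .roiRows(roi); cols <- .roiCols(roi)
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2])
    stop(sprintf("ROI rows %d..%d cols %d..%d outside image %d x %d",
                 min(rows), max(rows), min(cols), max(cols), d[1], d[2]))
  block <- cube@data[rows, cols, , drop = FALSE]
  n <- length(rows) * length(cols)
  m <- apply(block, 3, mean)
  sdPop <- apply(block, 3, function(v) sqrt(sum((v - mean(v))^2) / n))
  unit <- if (is(cube, "HSCube")) "dn" else "reflectance"
  nSat <- if (is(cube, "HSCube"))
    apply(cube@saturated[rows, cols, , drop = FALSE], 3, sum)
  else rep(0L, d[3])
  vals <- if (unit == "reflectance") pmin(pmax(m, -0.25), 2) else m
  list(mean = makeSpectrum(cube@grid, m, unit),
       sd = makeSpectrum(cube@grid, sdPop, if (unit == "dn") "dn" else "ratio"),
       nSaturated = as.integer(nSat))
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "SpectralGrid", function(object) {
  cat(sprintf("SpectralGrid: %g-%g nm, step %g nm (%s), %d bands\n",
              object@startNm, object@endNm, object@stepNm,
              object@convention, length(object@wavelengths)))
})

setMethod("show", "Spectrum", function(object) {
  v <- object@values
  cat(sprintf("Spectrum [%s]: %d bands over %g-%g nm, range [%.4g, %.4g]\n",
              object@unit, length(v), min(object@grid@wavelengths),
              max(object@grid@wavelengths), min(v), max(v)))
})

setMethod("show", "HSCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HSCube: %d x %d pixels x %d bands, %d-bit, %.4g%% saturated\n",
              d[1], d[2], d[3], object@bitDepth,
              100 * mean(object@saturated)))
  if (length(object@artefactBands))
    cat("  filter-transition artefact flagged in", length(object@artefactBands),
        "band(s)\n")
})

setMethod("show", "ReflectanceCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("ReflectanceCube: %d x %d pixels x %d bands, %.4g%% invalid\n",
              d[1], d[2], d[3], 100 * mean(object@invalidMask)))
})

setMethod("show", "ExposureProfile", function(object) {
  cat(sprintf("ExposureProfile [%s]: %d bands, target %g DN, cap %g ms\n",
              object@strategy, length(object@tMs), object@targetDn,
              object@tMaxMs))
  cat(sprintf("  t: %.3g-%.3g ms, %d capped (low-sensitivity) band(s), total %.3g s\n",
              min(object@tMs), max(object@tMs), sum(object@lowSensitivity),
              sum(object@tMs) / 1000))
})

setMethod("show", "OpticalSystemModel", function(object) {
  cat(sprintf("OpticalSystemModel '%s': %s, throughput %.3g, %d-bit sensor\n",
              object@name, object@mode, object@throughput,
              object@sensor@bitDepth))
  show(object@grid)
  if (length(object@transitionRangeNm))
    cat(sprintf("  filter transition %g-%g nm (magnitude %.3g)\n",
                object@transitionRangeNm[1], object@transitionRangeNm[2],
                object@transitionMagnitude))
})

setMethod("show", "SceneTarget", function(object) {
  cat(sprintf("SceneTarget: %d x %d pixels, %d patches, %d bands\n",
              object@nrow, object@ncol, nrow(object@patches),
              length(object@grid@wavelengths)))
  if (length(object@grayscaleNominal))
    cat(sprintf("  grayscale: %d tiles, %.2g -> %.2g reflectance\n",
                length(object@grayscaleNominal),
                max(object@grayscaleNominal), min(object@grayscaleNominal)))
})

setMethod("show", "CharacterizationReport", function(object) {
  cat(sprintf("CharacterizationReport '%s'\n", object@systemName))
  if (!is.na(object@rmsePct))
    cat(sprintf("  RMSE vs reference: %.3g%%\n", object@rmsePct))
  if (length(object@drDb))
    cat(sprintf("  DR:  global %.3g dB (max %.3g dB)\n",
                object@drGlobalDb, max(object@drDb, na.rm = TRUE)))
  if (length(object@snrDb))
    cat(sprintf("  SNR: global %.3g dB (max %.3g dB)\n",
                object@snrGlobalDb, max(object@snrDb, na.rm = TRUE)))
  if (length(object@oecf))
    cat(sprintf("  OECF: max deviation %.4g, R2 %.4g\n",
                object@oecf$deviation, object@oecf$r2))
  if (length(object@interbandPct))
    cat(sprintf("  inter-band RMSE: mean %.3g%%\n", object@interbandMeanPct))
})
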