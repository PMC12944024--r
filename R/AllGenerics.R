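#' Band-center wavelengths of an object
#'
#' @param x an object with a spectral axis.
#' @return numeric vector of wavelengths in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Number of spectral bands of an object
#'
#' @param x an object with a spectral axis.
#' @return integer band count.
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))

#' Per-band values of a Spectrum
#'
#' @param x a [Spectrum-class].
#' @return numeric vector.
#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))

#' Unit tag of a Spectrum
#'
#' @param x a [Spectrum-class].
#' @return character scalar.
#' @export
setGeneric("spectrumUnit", function(x) standardGeneric("spectrumUnit"))

#' Raw data array of a cube
#'
#' @param x an [HSCube-class] or [ReflectanceCube-class].
#' @return rows x cols x bands array.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' Sensor bit depth of a cube
#'
#' @param x an [HSCube-class].
#' @return integer (10 or 12).
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' Per-band exposure times of a cube or profile
#'
#' @param x an [HSCube-class] or [ExposureProfile-class].
#' @return numeric vector in ms.
#' @export
setGeneric("exposureTimes", function(x) standardGeneric("exposureTimes"))

#' Saturation mask of a cube
#'
#' @param x an [HSCube-class].
#' @return logical array, TRUE where the voxel sits at the top code value.
#' @export
setGeneric("saturatedMask", function(x) standardGeneric("saturatedMask"))

#' Invalid-voxel mask of a calibrated cube
#'
#' @param x a [ReflectanceCube-class].
#' @return logical array.
#' @export
setGeneric("invalidMask", function(x) standardGeneric("invalidMask"))

#' Bands flagged as affected by the filter-transition artefact
#'
#' @param x an [HSCube-class].
#' @return integer vector of band indices (possibly empty).
#' @export
setGeneric("artefactBands", function(x) standardGeneric("artefactBands"))

#' Low-sensitivity (capped) band flags of an exposure profile
#'
#' @param x an [ExposureProfile-class].
#' @return logical vector, TRUE where the uncapped solution exceeded the cap.
#' @export
setGeneric("lowSensitivityBands", function(x) standardGeneric("lowSensitivityBands"))

#' Total acquisition time of an exposure profile
#'
#' @param profile an [ExposureProfile-class] or a numeric vector of per-band
#'   exposures in ms.
#' @param overheadMs fixed per-band overhead in ms (filter tuning, readout);
#'   default 0.
#' @return total time in seconds: `(sum(t) + N * overheadMs) / 1000`.
#' @examples
#' totalAcquisitionTime(rep(250, 90))  # 22.5 s
#' @export
setGeneric("totalAcquisitionTime",
  function(profile, overheadMs = 0) standardGeneric("totalAcquisitionTime"))
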