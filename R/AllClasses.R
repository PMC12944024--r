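#' @import methods
NULL

.units <- c("reflectance", "dn", "db", "ms", "ratio", "arbitrary")

#' SpectralGrid: an equally spaced wavelength axis
#'
#' An ordered axis of band-center wavelengths in nanometres with a fixed
#' step and an endpoint convention. Under the `"closed"` convention both
#' endpoints are band centers, giving `(end - start)/step + 1` bands; under
#' `"half_open"` the upper endpoint is excluded, giving `(end - start)/step`
#' bands. Both conventions are first-class because tunable-filter systems
#' are specified both ways in practice (e.g. 90 bands of 5 nm over
#' 650--1100 nm, but 109 bands over the closed 460--1000 nm range).
#'
#' @slot startNm,endNm span of the axis in nm (`startNm < endNm`).
#' @slot stepNm band spacing in nm (> 0; the span must be divisible by it).
#' @slot convention `"closed"` or `"half_open"`.
#' @slot wavelengths the band-center wavelengths, strictly increasing.
#' @seealso [makeGrid()]
#' @export
setClass("SpectralGrid",
  representation(startNm = "numeric", endNm = "numeric", stepNm = "numeric",
                 convention = "character", wavelengths = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@startNm) != 1 || length(object@endNm) != 1 ||
        length(object@stepNm) != 1)
      msg <- c(msg, "startNm, endNm, stepNm must be scalars")
    if (!object@convention %in% c("closed", "half_open"))
      msg <- c(msg, "convention must be 'closed' or 'half_open'")
    if (object@stepNm <= 0) msg <- c(msg, "stepNm must be > 0")
    if (object@startNm >= object@endNm) msg <- c(msg, "startNm must be < endNm")
    wl <- object@wavelengths
    if (length(wl) < 1) msg <- c(msg, "empty wavelength axis")
    if (length(wl) > 1) {
      d <- diff(wl)
      if (any(d <= 0)) msg <- c(msg, "wavelengths must be strictly increasing")
      if (any(abs(d - object@stepNm) > 1e-6))
        msg <- c(msg, "wavelengths must be equally spaced by stepNm")
    }
    span <- object@endNm - object@startNm
    expected <- if (object@convention == "closed")
      round(span / object@stepNm) + 1 else round(span / object@stepNm)
    if (length(wl) != expected)
      msg <- c(msg, sprintf("band count %d does not match the %s convention (%d)",
                            length(wl), object@convention, expected))
    if (length(msg)) msg else TRUE
  })

#' Spectrum: per-band scalar values on a SpectralGrid
#'
#' A unit-tagged vector of one value per band. Units are `"reflectance"`
#' (fraction, nominally in \[0, 1\]; calibrated values may overshoot 1
#' slightly from noise and are retained, not clipped), `"dn"` (digital
#' numbers), `"db"`, `"ms"`, `"ratio"` (dimensionless, e.g. after min--max
#' normalization) or `"arbitrary"`.
#'
#' @slot grid a [SpectralGrid-class].
#' @slot values one numeric value per band of `grid`.
#' @slot unit unit tag, see above.
#' @seealso [makeSpectrum()], [reflectanceOvershoot()]
#' @export
setClass("Spectrum",
  representation(grid = "SpectralGrid", values = "numeric", unit = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@values) != length(object@grid@wavelengths))
      msg <- c(msg, "length(values) must equal the band count of the grid")
    if (!object@unit %in% .units)
      msg <- c(msg, paste("unit must be one of:", paste(.units, collapse = ", ")))
    if (object@unit == "reflectance" && length(object@values) &&
        any(object@values < -0.25 | object@values > 2, na.rm = TRUE))
      msg <- c(msg, "reflectance values grossly outside [0, 1] (allowed noise overshoot exceeded)")
    if (length(msg)) msg else TRUE
  })

#' HSCube: a raw digital-number hyperspectral cube
#'
#' Band-sequential rows x cols x bands integer cube with wavelength
#' metadata, per-band exposure times and a saturation mask. Digital numbers
#' are bounded by the sensor bit depth; a voxel is saturated exactly when it
#' sits at the top code value `2^bitDepth - 1`.
#'
#' @slot data rows x cols x bands array of digital numbers.
#' @slot grid a [SpectralGrid-class] (one wavelength per band).
#' @slot bitDepth 10 or 12.
#' @slot exposureMs per-band exposure time in ms.
#' @slot saturated logical array, same dimensions as `data`.
#' @slot artefactBands integer indices of bands flagged as perturbed by the
#'   filter-transition artefact (empty when none).
#' @export
setClass("HSCube",
  representation(data = "array", grid = "SpectralGrid", bitDepth = "integer",
                 exposureMs = "numeric", saturated = "array",
                 artefactBands = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3) msg <- c(msg, "data must be a rows x cols x bands array")
    nb <- length(object@grid@wavelengths)
    if (length(d) == 3 && d[3] != nb)
      msg <- c(msg, "third dimension of data must equal the grid band count")
    if (!object@bitDepth %in% c(10L, 12L))
      msg <- c(msg, "bitDepth must be 10 or 12")
    if (length(object@exposureMs) != nb)
      msg <- c(msg, "exposureMs must have one entry per band")
    maxDn <- 2^object@bitDepth - 1
    if (any(object@data < 0) || any(object@data > maxDn))
      msg <- c(msg, sprintf("DN values must lie in [0, %d]", maxDn))
    if (!identical(dim(object@saturated), d))
      msg <- c(msg, "saturated mask must match data dimensions")
    else if (!isTRUE(all(object@saturated == (object@data == maxDn))))
      msg <- c(msg, "saturated mask must be TRUE exactly where DN equals the top code")
    if (length(object@artefactBands) &&
        (any(object@artefactBands < 1) || any(object@artefactBands > nb)))
      msg <- c(msg, "artefactBands out of range")
    if (length(msg)) msg else TRUE
  })

#' ReflectanceCube: a calibrated reflectance cube
#'
#' Per-voxel reflectance fractions after white/dark calibration. Voxels
#' where the calibration was numerically unstable (white - dark at or below
#' the stability threshold) or where raw/white data were saturated are
#' masked invalid (value 0, `invalidMask` TRUE) rather than silently
#' clipped; valid values are finite and may exceed 1 slightly from noise.
#'
#' @slot data rows x cols x bands numeric array of reflectance fractions.
#' @slot grid a [SpectralGrid-class].
#' @slot invalidMask logical array marking division-unstable/saturated voxels.
#' @export
setClass("ReflectanceCube",
  representation(data = "array", grid = "SpectralGrid", invalidMask = "array"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3) msg <- c(msg, "data must be a rows x cols x bands array")
    if (length(d) == 3 && d[3] != length(object@grid@wavelengths))
      msg <- c(msg, "third dimension must equal the grid band count")
    if (!identical(dim(object@invalidMask), d))
      msg <- c(msg, "invalidMask must match data dimensions")
    if (any(!is.finite(object@data)))
      msg <- c(msg, "reflectance values must be finite (invalid voxels are masked, not NaN)")
    if (length(msg)) msg else TRUE
  })

#' RegionOfInterest: a square pixel region
#'
#' @slot centerRow,centerCol center pixel (1-based).
#' @slot size side length in pixels (>= 1). For even sizes the region
#'   extends one pixel further below/right of the center.
#' @seealso [makeRoi()], [extractRoiSpectrum()]
#' @export
setClass("RegionOfInterest",
  representation(centerRow = "integer", centerCol = "integer", size = "integer"),
  validity = function(object) {
    if (object@size < 1L) "size must be >= 1"
    else if (object@centerRow < 1L || object@centerCol < 1L) "center must be >= 1"
    else TRUE
  })

# ---- optical chain models -------------------------------------------------

#' IlluminantModel: relative spectral power of a light source
#'
#' @slot kind `"halogen_broadband"`, `"led_highcri"`, `"dual"` or `"custom"`.
#' @slot fun a vectorized function E(lambda nm) -> relative power (>= 0,
#'   arbitrary units).
#' @export
setClass("IlluminantModel",
  representation(kind = "character", fun = "function"))

#' PassbandModel: tunable narrow-band filter transmission
#'
#' Transmission around a tuned center wavelength. The default shape is a
#' Gaussian with a wavelength-dependent FWHM (LCTF bandwidth grows with
#' wavelength); a rectangular shape is provided for closed-form checks.
#'
#' @slot shape `"gaussian"` or `"rect"`.
#' @slot fwhmFun function(center nm) -> FWHM in nm.
#' @slot peakTransmission peak in-band transmission fraction in (0, 1\].
#' @slot leakage out-of-band transmission floor fraction (>= 0, small).
#' @slot rangeNm tuning range (lo, hi) in nm.
#' @export
setClass("PassbandModel",
  representation(shape = "character", fwhmFun = "function",
                 peakTransmission = "numeric", leakage = "numeric",
                 rangeNm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@shape %in% c("gaussian", "rect")) msg <- c(msg, "unknown shape")
    if (object@peakTransmission <= 0 || object@peakTransmission > 1)
      msg <- c(msg, "peakTransmission must be in (0, 1]")
    if (object@leakage < 0 || object@leakage > 0.05)
      msg <- c(msg, "leakage must be a small non-negative fraction")
    if (length(object@rangeNm) != 2 || diff(object@rangeNm) <= 0)
      msg <- c(msg, "rangeNm must be (lo, hi)")
    if (length(msg)) msg else TRUE
  })

#' SensorModel: quantum efficiency, gain and noise of the camera
#'
#' @slot qeFun function(lambda nm) -> quantum efficiency fraction in \[0, 1\].
#' @slot bitDepth 10 or 12.
#' @slot gain DN per detected unit (photoelectron); shot-noise variance of
#'   the signal in DN^2 is `gain * signalDn`.
#' @slot readNoiseRms read noise RMS in DN.
#' @slot darkRateDnPerMs dark signal accumulation in DN per ms.
#' @slot darkOffsetDn fixed dark offset in DN.
#' @export
setClass("SensorModel",
  representation(qeFun = "function", bitDepth = "integer", gain = "numeric",
                 readNoiseRms = "numeric", darkRateDnPerMs = "numeric",
                 darkOffsetDn = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@bitDepth %in% c(10L, 12L)) msg <- c(msg, "bitDepth must be 10 or 12")
    if (object@gain <= 0) msg <- c(msg, "gain must be > 0")
    if (object@readNoiseRms < 0 || object@darkRateDnPerMs < 0 ||
        object@darkOffsetDn < 0) msg <- c(msg, "noise terms must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' OpticalSystemModel: the complete acquisition chain
#'
#' Illuminant, tunable passband, sensor, optical throughput, filtering mode
#' and (optionally) a filter-transition artefact band range. The expected
#' signal for a band is `gain * throughput * t * integral(E T QE) * R`,
#' added to the dark level and clipped to the sensor code range.
#'
#' @slot name preset/system name.
#' @slot illuminant an [IlluminantModel-class].
#' @slot passband a [PassbandModel-class].
#' @slot sensor a [SensorModel-class].
#' @slot throughput optical throughput fraction in (0, 1].
#' @slot mode `"emission_filtering"` or `"reception_filtering"`.
#' @slot transitionRangeNm numeric(0) or (lo, hi) nm of the dual-filter
#'   transition artefact.
#' @slot transitionMagnitude multiplicative perturbation applied inside the
#'   transition range (1 = no artefact).
#' @slot grid default acquisition [SpectralGrid-class] for the system.
#' @export
setClass("OpticalSystemModel",
  representation(name = "character", illuminant = "IlluminantModel",
                 passband = "PassbandModel", sensor = "SensorModel",
                 throughput = "numeric", mode = "character",
                 transitionRangeNm = "numeric", transitionMagnitude = "numeric",
                 grid = "SpectralGrid"),
  validity = function(object) {
    msg <- character()
    if (object@throughput <= 0 || object@throughput > 1)
      msg <- c(msg, "throughput must be in (0, 1]")
    if (!object@mode %in% c("emission_filtering", "reception_filtering"))
      msg <- c(msg, "mode must be emission_filtering or reception_filtering")
    if (!length(object@transitionRangeNm) %in% c(0, 2))
      msg <- c(msg, "transitionRangeNm must be empty or (lo, hi)")
    if (length(object@transitionRangeNm) == 2 &&
        diff(object@transitionRangeNm) <= 0)
      msg <- c(msg, "transitionRangeNm must be increasing")
    if (object@transitionMagnitude <= 0)
      msg <- c(msg, "transitionMagnitude must be > 0")
    if (length(msg)) msg else TRUE
  })

#' SceneTarget: a synthetic flat test target
#'
#' A rectangular scene of labelled, non-overlapping patches, each with its
#' own reflectance spectrum, over a uniform background. Generators exist
#' for a color-checker style chart with a 12-step grayscale
#' ([makeRezCheckerScene()]) and for uniform (flat) targets
#' ([makeFlatScene()]).
#'
#' @slot nrow,ncol scene size in pixels.
#' @slot grid the [SpectralGrid-class] all patch spectra live on.
#' @slot patches data.frame with columns `label, row1, row2, col1, col2`.
#' @slot spectra named list of [Spectrum-class], one per patch label.
#' @slot background background [Spectrum-class].
#' @slot grayscaleNominal named numeric of nominal reflectances for
#'   grayscale tiles (empty for scenes without a grayscale).
#' @export
setClass("SceneTarget",
  representation(nrow = "integer", ncol = "integer", grid = "SpectralGrid",
                 patches = "data.frame", spectra = "list",
                 background = "Spectrum", grayscaleNominal = "numeric"),
  validity = function(object) {
    msg <- character()
    p <- object@patches
    need <- c("label", "row1", "row2", "col1", "col2")
    if (!all(need %in% names(p))) return("patches must have label,row1,row2,col1,col2")
    if (nrow(p)) {
      if (any(p$row1 < 1 | p$col1 < 1 | p$row2 > object@nrow | p$col2 > object@ncol))
        msg <- c(msg, "patches must lie inside the scene bounds")
      if (any(p$row1 > p$row2 | p$col1 > p$col2))
        msg <- c(msg, "degenerate patch rectangle")
      if (nrow(p) > 1) {
        for (i in seq_len(nrow(p) - 1)) for (j in seq(i + 1, nrow(p))) {
          if (p$row1[i] <= p$row2[j] && p$row1[j] <= p$row2[i] &&
              p$col1[i] <= p$col2[j] && p$col1[j] <= p$col2[i]) {
            msg <- c(msg, sprintf("patches '%s' and '%s' overlap", p$label[i], p$label[j]))
            break
          }
        }
      }
      if (!all(p$label %in% names(object@spectra)))
        msg <- c(msg, "every patch label needs a spectrum")
    }
    if (length(msg)) msg else TRUE
  })

#' MotionModel: inter-frame scene motion during spatio-spectral scanning
#'
#' Per-frame spatial shift of the scene while the sensor sweeps diagonal
#' spatial--spectral planes. Amplitude 0 reproduces the static case
#' exactly. The `"sine"` schedule emulates periodic (respiratory) motion
#' and is deterministic; `"random_walk"` draws seeded Gaussian steps;
#' `"constant"` shifts by the amplitude on every frame.
#'
#' @slot amplitudePx shift amplitude in pixels (>= 0).
#' @slot axis `"row"` (vertical) or `"col"` (horizontal).
#' @slot schedule `"sine"`, `"random_walk"` or `"constant"`.
#' @slot cycles for `"sine"`: number of motion periods per scan.
#' @export
setClass("MotionModel",
  representation(amplitudePx = "numeric", axis = "character",
                 schedule = "character", cycles = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@amplitudePx < 0) msg <- c(msg, "amplitudePx must be >= 0")
    if (!object@axis %in% c("row", "col")) msg <- c(msg, "axis must be 'row' or 'col'")
    if (!object@schedule %in% c("sine", "random_walk", "constant"))
      msg <- c(msg, "unknown schedule")
    if (length(msg)) msg else TRUE
  })

# ---- exposure control -----------------------------------------------------

#' EfficiencyCurve: per-band system sensitivity from white captures
#'
#' Sampled system efficiency, in DN above dark per millisecond, measured
#' from white-reference captures (typically every 20 nm to keep the
#' characterization short).
#'
#' @slot wavelengthsNm sample wavelengths (knots), nm.
#' @slot dnPerMs efficiency at each knot (>= 0).
#' @slot refExposureMs the exposure the white captures used.
#' @export
setClass("EfficiencyCurve",
  representation(wavelengthsNm = "numeric", dnPerMs = "numeric",
                 refExposureMs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@wavelengthsNm) != length(object@dnPerMs))
      msg <- c(msg, "wavelengthsNm and dnPerMs must have equal length")
    if (length(object@wavelengthsNm) == 0) msg <- c(msg, "empty efficiency curve")
    if (any(object@dnPerMs < 0)) msg <- c(msg, "efficiency must be >= 0")
    if (is.unsorted(object@wavelengthsNm, strictly = TRUE))
      msg <- c(msg, "wavelengths must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' ExposureProfile: per-band exposure times
#'
#' The result of solving per-band exposure towards a target digital number
#' with a cap. Bands whose uncapped solution exceeds the cap (low system
#' sensitivity) carry a flag; the uncapped solution is retained so that
#' densification to a finer grid interpolates the physical curve before
#' re-applying the cap.
#'
#' @slot grid the [SpectralGrid-class] the profile is defined on.
#' @slot tMs per-band exposure in ms (0 < t <= tMaxMs).
#' @slot tUncappedMs the uncapped solution target/efficiency (bounded for
#'   numerical sanity at zero-efficiency bands).
#' @slot targetDn the target digital number (signal above dark).
#' @slot tMaxMs the exposure cap in ms.
#' @slot strategy `"constant"`, `"short_limit"`, `"long_limit"` or `"custom"`.
#' @slot lowSensitivity per-band flag, TRUE exactly where the uncapped
#'   solution exceeds the cap.
#' @export
setClass("ExposureProfile",
  representation(grid = "SpectralGrid", tMs = "numeric", tUncappedMs = "numeric",
                 targetDn = "numeric", tMaxMs = "numeric", strategy = "character",
                 lowSensitivity = "logical"),
  validity = function(object) {
    msg <- character()
    nb <- length(object@grid@wavelengths)
    if (length(object@tMs) != nb) msg <- c(msg, "tMs must have one entry per band")
    if (length(object@tUncappedMs) != nb)
      msg <- c(msg, "tUncappedMs must have one entry per band")
    if (length(object@lowSensitivity) != nb)
      msg <- c(msg, "lowSensitivity must have one entry per band")
    if (object@tMaxMs <= 0) msg <- c(msg, "tMaxMs must be > 0")
    if (length(object@tMs) && (any(object@tMs <= 0) ||
        any(object@tMs > object@tMaxMs + 1e-9)))
      msg <- c(msg, "exposures must satisfy 0 < t <= tMaxMs")
    if (!object@strategy %in% c("constant", "short_limit", "long_limit", "custom"))
      msg <- c(msg, "unknown strategy")
    if (length(msg)) msg else TRUE
  })

#' CharacterizationReport: the QC metric bundle for one system
#'
#' Holds spectral RMSE against a reference standard (percent), per-band and
#' global dynamic range and SNR in dB, OECF points with a linearity
#' deviation, the inter-band RMSE series, and system metadata for
#' comparison tables. Global dB values are unweighted means over bands;
#' bands excluded for zero denominators are listed in `meta$excluded`.
#'
#' @slot systemName system label.
#' @slot rmsePct RMSE against the reference spectrum, percent (NA if not measured).
#' @slot drDb per-band dynamic range, dB.
#' @slot drGlobalDb unweighted mean of `drDb`.
#' @slot snrDb per-band SNR, dB.
#' @slot snrGlobalDb unweighted mean of `snrDb`.
#' @slot oecf list from [oecf()] (points, per-band residuals, deviation, r2).
#' @slot interbandPct inter-band RMSE series, percent (band 2..N).
#' @slot interbandMeanPct mean of the series.
#' @slot meta list: band count, spectral range, FWHM summary, spatial size,
#'   bit depth, warnings collected during characterization.
#' @export
setClass("CharacterizationReport",
  representation(systemName = "character", rmsePct = "numeric",
                 drDb = "numeric", drGlobalDb = "numeric",
                 snrDb = "numeric", snrGlobalDb = "numeric",
                 oecf = "list", interbandPct = "numeric",
                 interbandMeanPct = "numeric", meta = "list"))
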