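# Forward model of the acquisition chain:
#   illuminant E(lambda) -> tunable passband T(lambda; center) -> scene
#   reflectance R -> sensor QE(lambda), gain, noise -> quantized DN.
# Photon units are abstracted: the sensor gain folds absolute photon flux
# into DN per ms, so only relative radiometry (DN levels and ratios) is
# modelled.

#' Construct an illuminant model
#'
#' Presets: `"halogen_broadband"`, a smooth 3200 K thermal-like emitter
#' supported on 400--1750 nm; `"led_highcri"`, a flat high-CRI white LED
#' supported on 420--700 nm with soft spectral edges. For `"custom"`,
#' supply `fun`.
#'
#' @param kind preset name or `"custom"`.
#' @param fun for `"custom"`: vectorized E(lambda nm) -> relative power >= 0.
#' @return an [IlluminantModel-class].
#' @export
makeIlluminant <- function(kind = c("halogen_broadband", "led_highcri", "custom"),
                           fun = NULL) {
  kind <- match.arg(kind)
  if (kind == "halogen_broadband") {
    fun <- function(l) {
      # Wien-like 3200 K shape, normalized near its peak, zero outside support
      p <- (l * 1e-9)^-5 / expm1(1.4388e-2 / (l * 1e-9) / 3200)
      pk <- (905e-9)^-5 / expm1(1.4388e-2 / 905e-9 / 3200)
      ifelse(l >= 400 & l <= 1750, p / pk, 0)
    }
  } else if (kind == "led_highcri") {
    fun <- function(l) {
      edge <- function(x) 1 / (1 + exp(-x / 6))
      ifelse(l >= 400 & l <= 720, edge(l - 430) * edge(690 - l), 0)
    }
  } else if (is.null(fun)) stop("custom illuminant needs 'fun'")
  new("IlluminantModel", kind = kind, fun = fun)
}

# dual-source illuminant used by the two-filter clinical presets: LED for
# the visible channel plus an attenuated halogen for the NIR channel
.dualIlluminant <- function(ledWeight = 1, halogenWeight = 0.9) {
  led <- makeIlluminant("led_highcri")@fun
  hal <- makeIlluminant("halogen_broadband")@fun
  new("IlluminantModel", kind = "dual",
      fun = function(l) ledWeight * led(l) +
        halogenWeight * hal(l) * ifelse(l >= 500 & l <= 1600, 1, 0))
}

#' Construct a tunable passband model
#'
#' The default Gaussian passband has a wavelength-dependent FWHM ramping
#' linearly from `fwhmNm[1]` at the low end of the tuning range to
#' `fwhmNm[2]` at the high end (LCTF bandwidth grows with wavelength). A
#' rectangular shape (`shape = "rect"`, full transmission over one FWHM) is
#' provided for closed-form validation.
#'
#' @param rangeNm tuning range (lo, hi) in nm.
#' @param fwhmNm FWHM in nm: a scalar or (low, high) ramp endpoints.
#' @param peakTransmission peak transmission fraction.
#' @param leakage out-of-band transmission floor.
#' @param shape `"gaussian"` (default) or `"rect"`.
#' @return a [PassbandModel-class].
#' @export
makePassband <- function(rangeNm, fwhmNm = c(9, 24), peakTransmission = 0.35,
                         leakage = 1e-4, shape = c("gaussian", "rect")) {
  shape <- match.arg(shape)
  fwhmNm <- rep_len(fwhmNm, 2)
  lo <- rangeNm[1]; hi <- rangeNm[2]
  fwhmFun <- function(center) {
    f <- fwhmNm[1] + (fwhmNm[2] - fwhmNm[1]) *
      pmin(pmax((center - lo) / (hi - lo), 0), 1)
    f
  }
  new("PassbandModel", shape = shape, fwhmFun = fwhmFun,
      peakTransmission = peakTransmission, leakage = leakage,
      rangeNm = as.numeric(rangeNm))
}

# in-band transmission at wavelengths l for a filter tuned to `center`
# (leakage handled separately as a broad-band term)
.passbandT <- function(passband, center, l) {
  fwhm <- passband@fwhmFun(center)
  if (passband@shape == "gaussian") {
    passband@peakTransmission * exp(-4 * log(2) * (l - center)^2 / fwhm^2)
  } else {
    passband@peakTransmission * as.numeric(abs(l - center) <= fwhm / 2)
  }
}

#' Construct a sensor model
#'
#' @param qeFun vectorized quantum-efficiency function(lambda nm) in \[0, 1\].
#' @param bitDepth 10 or 12.
#' @param gain DN per photoelectron; shot variance in DN^2 is `gain * signal`.
#' @param readNoiseRms read noise RMS, DN.
#' @param darkRateDnPerMs dark accumulation, DN/ms.
#' @param darkOffsetDn fixed dark offset, DN.
#' @return a [SensorModel-class].
#' @export
makeSensor <- function(qeFun, bitDepth, gain = 0.2, readNoiseRms = 0.5,
                       darkRateDnPerMs = 0.01, darkOffsetDn = 40) {
  new("SensorModel", qeFun = qeFun, bitDepth = as.integer(bitDepth),
      gain = gain, readNoiseRms = readNoiseRms,
      darkRateDnPerMs = darkRateDnPerMs, darkOffsetDn = darkOffsetDn)
}

# smooth shape-preserving QE curve through anchor points (PCHIP, so the
# curve stays within the anchor envelope and has no spurious ripples)
.qeFromAnchors <- function(anchorNm, anchorQe) {
  function(l) {
    lc <- pmin(pmax(l, min(anchorNm)), max(anchorNm))
    pmin(pmax(pracma::pchip(anchorNm, anchorQe, lc), 0), 1)
  }
}

#' Assemble an optical system model
#'
#' @param name system label.
#' @param illuminant an [IlluminantModel-class].
#' @param passband a [PassbandModel-class].
#' @param sensor a [SensorModel-class].
#' @param grid default acquisition [SpectralGrid-class].
#' @param throughput optical throughput fraction in (0, 1].
#' @param mode `"emission_filtering"` or `"reception_filtering"`.
#' @param transitionRangeNm numeric(0) (no artefact) or (lo, hi) nm.
#' @param transitionMagnitude multiplicative perturbation inside the range.
#' @return an [OpticalSystemModel-class].
#' @export
makeOpticalSystem <- function(name, illuminant, passband, sensor, grid,
                              throughput = 1, mode = "emission_filtering",
                              transitionRangeNm = numeric(),
                              transitionMagnitude = 1) {
  new("OpticalSystemModel", name = name, illuminant = illuminant,
      passband = passband, sensor = sensor, throughput = throughput,
      mode = mode, transitionRangeNm = as.numeric(transitionRangeNm),
      transitionMagnitude = transitionMagnitude, grid = grid)
}

#' Per-band signal rate of a system
#'
#' The expected signal in DN per ms per unit reflectance for a filter tuned
#' to each wavelength: `gain * throughput * integral(E(l) T(l) QE(l) dl)`,
#' evaluated by trapezoidal quadrature over the passband (plus the
#' broadband leakage term).
#'
#' @param system an [OpticalSystemModel-class].
#' @param centersNm tuned center wavelengths, nm.
#' @return numeric vector, DN/ms per unit reflectance.
#' @export
bandSignalRate <- function(system, centersNm) {
  pb <- system@passband; sn <- system@sensor; E <- system@illuminant@fun
  leakTerm <- 0
  if (pb@leakage > 0) {
    lg <- seq(400, 1750, by = 5)
    leakTerm <- pb@leakage * pracma::trapz(lg, E(lg) * sn@qeFun(lg))
  }
  vapply(centersNm, function(cen) {
    fw <- pb@fwhmFun(cen)
    half <- if (pb@shape == "gaussian") 2.5 * fw else fw / 2
    l <- seq(cen - half, cen + half, by = min(0.25, fw / 24))
    core <- pracma::trapz(l, E(l) * .passbandT(pb, cen, l) * sn@qeFun(l))
    sn@gain * system@throughput * (core + leakTerm)
  }, numeric(1))
}

# multiplicative transition-artefact factor per band (1 where unaffected)
.transitionFactor <- function(system, centersNm, jitterSd = 0) {
  f <- rep(1, length(centersNm))
  if (length(system@transitionRangeNm) == 2 && system@transitionMagnitude != 1) {
    idx <- centersNm >= system@transitionRangeNm[1] &
      centersNm <= system@transitionRangeNm[2]
    m <- system@transitionMagnitude
    if (jitterSd > 0) m <- 1 + (m - 1) * (1 + stats::rnorm(1, 0, jitterSd))
    f[idx] <- m
  }
  f
}

#' Expected digital number of the linear radiometric model
#'
#' `DN = clip(darkOffset + darkRate * t + rate(band) * t * R, 0, 2^b - 1)`
#' with `rate` from [bandSignalRate()]; affine in exposure and reflectance
#' below saturation.
#'
#' @param system an [OpticalSystemModel-class].
#' @param bandNm tuned center wavelength, nm (scalar).
#' @param reflectance scene reflectance fraction (vectorized).
#' @param exposureMs exposure in ms, > 0.
#' @return expected DN (real, unquantized).
#' @export
expectedDn <- function(system, bandNm, reflectance, exposureMs) {
  stopifnot(exposureMs > 0)
  sn <- system@sensor
  rate <- bandSignalRate(system, bandNm) * .transitionFactor(system, bandNm)
  dn <- sn@darkOffsetDn + sn@darkRateDnPerMs * exposureMs +
    rate * exposureMs * reflectance
  pmin(pmax(dn, 0), 2^sn@bitDepth - 1)
}

# ---- scene rasterization --------------------------------------------------

# reflectance map (matrix) of a scene at band index b
.sceneBandMap <- function(scene, b) {
  m <- matrix(scene@background@values[b], scene@nrow, scene@ncol)
  p <- scene@patches
  for (i in seq_len(nrow(p)))
    m[p$row1[i]:p$row2[i], p$col1[i]:p$col2[i]] <-
      scene@spectra[[p$label[i]]]@values[b]
  m
}

# one noisy (or noiseless) frame: signal DN matrix -> quantized DN matrix
.sensorFrame <- function(signalDn, sensor, exposureMs, noise = TRUE) {
  dark <- sensor@darkOffsetDn + sensor@darkRateDnPerMs * exposureMs
  if (noise) {
    ne <- pmax(signalDn, 0) / sensor@gain
    shot <- matrix(stats::rpois(length(ne), as.vector(ne)) * sensor@gain,
                   nrow(signalDn), ncol(signalDn))
    dn <- dark + shot + stats::rnorm(length(ne), 0, sensor@readNoiseRms)
  } else {
    dn <- dark + signalDn
  }
  matrix(pmin(pmax(round(dn), 0), 2^sensor@bitDepth - 1),
         nrow(signalDn), ncol(signalDn))
}

.checkSameGrid <- function(a, b, what = "objects") {
  wa <- wavelengths(a); wb <- wavelengths(b)
  if (length(wa) != length(wb) || any(abs(wa - wb) > 1e-6))
    stop(what, " must share the same spectral grid")
}

#' Simulate a spectral-scanning acquisition
#'
#' Captures the full frame band by band (one tuned filter position per
#' band) with Poisson shot noise, Gaussian read noise, dark level and
#' quantization to the sensor bit depth. The same seed reproduces the cube
#' bit-exactly. If the system carries a filter-transition artefact, the
#' affected bands are perturbed multiplicatively (with a small seeded
#' per-acquisition jitter, so the artefact does not cancel exactly in
#' white-reference calibration) and flagged in the cube metadata.
#'
#' Draw order (fixed for reproducibility): the transition jitter first,
#' then per band: shot noise for all pixels, then read noise for all pixels.
#'
#' @param scene a [SceneTarget-class].
#' @param system an [OpticalSystemModel-class].
#' @param profile an [ExposureProfile-class] on the same grid as the scene.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param noise set `FALSE` for the noiseless limit (expected DN, rounded).
#' @return an [HSCube-class].
#' @export
simulateCube <- function(scene, system, profile, seed = NULL, noise = TRUE) {
  .checkSameGrid(scene, profile, "scene and profile")
  if (!is.null(seed)) set.seed(seed)
  wl <- wavelengths(scene@grid)
  rates <- bandSignalRate(system, wl) *
    .transitionFactor(system, wl, jitterSd = if (noise) 0.3 else 0)
  nb <- length(wl)
  arr <- array(0L, dim = c(scene@nrow, scene@ncol, nb))
  for (b in seq_len(nb)) {
    sig <- rates[b] * profile@tMs[b] * .sceneBandMap(scene, b)
    arr[, , b] <- .sensorFrame(sig, system@sensor, profile@tMs[b], noise)
  }
  flagged <- if (length(system@transitionRangeNm) == 2 &&
                 system@transitionMagnitude != 1)
    which(wl >= system@transitionRangeNm[1] & wl <= system@transitionRangeNm[2])
  else integer()
  .newHSCube(arr, scene@grid, system@sensor@bitDepth, profile@tMs, flagged)
}

#' Construct a motion model
#'
#' @param amplitudePx shift amplitude in pixels (0 = static).
#' @param axis `"row"` (vertical artefacts) or `"col"`.
#' @param schedule `"sine"` (deterministic, periodic; default),
#'   `"random_walk"` (seeded Gaussian steps of SD `amplitudePx`), or
#'   `"constant"` (every frame shifted by the amplitude).
#' @param cycles motion periods per scan for `"sine"`.
#' @return a [MotionModel-class].
#' @export
makeMotionModel <- function(amplitudePx, axis = c("row", "col"),
                            schedule = c("sine", "random_walk", "constant"),
                            cycles = 3) {
  new("MotionModel", amplitudePx = amplitudePx, axis = match.arg(axis),
      schedule = match.arg(schedule), cycles = cycles)
}

# per-frame integer shifts for nFrames frames
.motionShifts <- function(motion, nFrames) {
  a <- motion@amplitudePx
  if (a == 0) return(rep(0L, nFrames))
  s <- switch(motion@schedule,
    sine = a * sin(2 * pi * motion@cycles * seq_len(nFrames) / nFrames),
    random_walk = cumsum(stats::rnorm(nFrames, 0, a)),
    constant = rep(a, nFrames))
  as.integer(round(s))
}

# shift a matrix along rows/cols by s pixels with edge clamping
.shiftMap <- function(m, s, axis) {
  if (s == 0) return(m)
  n <- if (axis == "row") nrow(m) else ncol(m)
  idx <- pmin(pmax(seq_len(n) - s, 1), n)
  if (axis == "row") m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
}

#' Simulate a spatio-spectral scanning acquisition
#'
#' Emulates a sensor whose spectral filters are aligned with sensor
#' columns: each frame captures a diagonal spatial--spectral plane, and
#' band `b` at column `c` is assembled from frame `b + c - 1`
#' (nearest-frame assignment). Between frames the scene shifts according
#' to the [MotionModel-class]; with zero amplitude the output reproduces
#' the spectral-scanning cube distribution exactly (identical noiseless
#' output). Scene motion therefore imprints column-dependent displacement
#' that differs between consecutive bands -- the vertical banding artefact
#' characteristic of this scanning mode.
#'
#' Draw order: transition jitter, then motion-schedule draws (random walk
#' only), then per band shot and read noise as in [simulateCube()].
#'
#' @inheritParams simulateCube
#' @param motion a [MotionModel-class].
#' @return an [HSCube-class].
#' @export
simulateSpatioScanCube <- function(scene, system, profile, motion,
                                   seed = NULL, noise = TRUE) {
  .checkSameGrid(scene, profile, "scene and profile")
  if (!is.null(seed)) set.seed(seed)
  wl <- wavelengths(scene@grid)
  rates <- bandSignalRate(system, wl) *
    .transitionFactor(system, wl, jitterSd = if (noise) 0.3 else 0)
  nb <- length(wl)
  nFrames <- nb + scene@ncol - 1L
  shifts <- .motionShifts(motion, nFrames)
  arr <- array(0L, dim = c(scene@nrow, scene@ncol, nb))
  cols <- seq_len(scene@ncol)
  for (b in seq_len(nb)) {
    map <- .sceneBandMap(scene, b)
    bandShifts <- shifts[b + cols - 1L]
    assembled <- matrix(0, scene@nrow, scene@ncol)
    for (s in unique(bandShifts)) {
      sel <- bandShifts == s
      shifted <- .shiftMap(map, s, motion@axis)
      assembled[, sel] <- shifted[, sel]
    }
    sig <- rates[b] * profile@tMs[b] * assembled
    arr[, , b] <- .sensorFrame(sig, system@sensor, profile@tMs[b], noise)
  }
  flagged <- if (length(system@transitionRangeNm) == 2 &&
                 system@transitionMagnitude != 1)
    which(wl >= system@transitionRangeNm[1] & wl <= system@transitionRangeNm[2])
  else integer()
  .newHSCube(arr, scene@grid, system@sensor@bitDepth, profile@tMs, flagged)
}

#' Inject a filter-transition artefact into a cube
#'
#' Multiplies the digital numbers of the bands whose centers fall inside
#' `bandRangeNm` by `magnitude` (dark level included; the perturbation is a
#' band-local gain error), re-quantizes, and flags the affected bands in
#' the cube metadata. `magnitude = 1` returns the cube unchanged apart
#' from the flags being set.
#'
#' @param cube an [HSCube-class].
#' @param bandRangeNm (lo, hi) in nm; must contain at least one band center.
#' @param magnitude multiplicative perturbation, > 0.
#' @return the perturbed [HSCube-class].
#' @export
injectFilterTransition <- function(cube, bandRangeNm, magnitude) {
  stopifnot(length(bandRangeNm) == 2, magnitude > 0)
  wl <- wavelengths(cube)
  idx <- which(wl >= bandRangeNm[1] & wl <= bandRangeNm[2])
  if (!length(idx))
    stop(sprintf("band range %g-%g nm contains no band of the %g-%g nm grid",
                 bandRangeNm[1], bandRangeNm[2], min(wl), max(wl)))
  arr <- cube@data
  maxDn <- 2^cube@bitDepth - 1
  for (b in idx)
    arr[, , b] <- pmin(pmax(round(arr[, , b] * magnitude), 0), maxDn)
  .newHSCube(arr, cube@grid, cube@bitDepth, cube@exposureMs,
             sort(union(cube@artefactBands, idx)))
}
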