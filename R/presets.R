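# System presets. Absolute photon flux is abstracted into the illuminant
# amplitude: each preset scales its illuminant so that the most sensitive
# band of its grid reaches a stated peak signal rate (DN/ms at unit
# reflectance), which pins the DN scale the way a real source power and
# lens aperture would.

.scaleSystemTo <- function(system, peakRateDnPerMs) {
  r <- max(bandSignalRate(system, wavelengths(system@grid)))
  base <- system@illuminant@fun
  k <- peakRateDnPerMs / r
  system@illuminant <- new("IlluminantModel", kind = system@illuminant@kind,
                           fun = function(l) k * base(l))
  system
}

#' Named optical-system presets
#'
#' * `"nir_lab_efs"` -- single NIR tunable filter (650--1100 nm tuning, 90
#'   bands of 5 nm, half-open), emission filtering (the filter shapes the
#'   illumination), halogen source, 10-bit NIR-enhanced sensor whose QE
#'   peaks at 0.60 near 600 nm and falls to 0.05 at 1000 nm. Full
#'   throughput.
#' * `"nir_lab_rfs"` -- the same optics with the filter on the reception
#'   path behind a long-working-distance beamsplitter: throughput is 12.5%
#'   of the emission preset (an 87.5% light deficit), so matching a given
#'   DN needs 8x the exposure.
#' * `"clinical_dual_lctf"` -- dual-filter clinical system: 460--1000 nm
#'   closed grid (109 bands of 5 nm), LED (visible) + halogen (NIR)
#'   illumination, 12-bit sensor with QE 0.72 over 525--580 nm, FWHM
#'   ramping so the grid average is 18 nm, and a filter-transition artefact
#'   over 720--740 nm where the two filter paths hand over.
#' * `"snapscan_like"` -- a spatio-spectral scanning benchmark: 470--900 nm,
#'   10-bit, narrow 7 nm FWHM, deliberately uneven per-band sensitivity and
#'   a low dark level (6 DN vs the clinical preset's 40 DN).
#'
#' @param name preset name.
#' @param peakRateDnPerMs optional override of the peak signal rate the
#'   illuminant is scaled to (DN/ms at unit reflectance).
#' @return an [OpticalSystemModel-class].
#' @examples
#' sys <- systemPreset("clinical_dual_lctf")
#' nBands(sys@grid)  # 109
#' @export
systemPreset <- function(name = c("nir_lab_efs", "nir_lab_rfs",
                                  "clinical_dual_lctf", "snapscan_like"),
                         peakRateDnPerMs = NULL) {
  name <- match.arg(name)
  if (name %in% c("nir_lab_efs", "nir_lab_rfs")) {
    rfs <- name == "nir_lab_rfs"
    qe <- .qeFromAnchors(
      c(400, 500, 600, 700, 800, 900, 1000, 1100),
      c(0.30, 0.50, 0.60, 0.52, 0.35, 0.17, 0.05, 0.02))
    sys <- makeOpticalSystem(
      name = name,
      illuminant = makeIlluminant("halogen_broadband"),
      passband = makePassband(c(650, 1100), fwhmNm = c(9, 24)),
      sensor = makeSensor(qe, bitDepth = 10, gain = 0.1, readNoiseRms = 1,
                          darkRateDnPerMs = 0.005, darkOffsetDn = 5),
      grid = makeGrid(650, 1100, 5, "half_open"),
      throughput = if (rfs) 0.125 else 1,
      mode = if (rfs) "reception_filtering" else "emission_filtering")
    # scale the shared source once, on the emission geometry, so the RFS
    # preset keeps the physical 8x deficit instead of being re-normalized
    full <- sys; full@throughput <- 1
    full <- .scaleSystemTo(full, peakRateDnPerMs %||% 3.2)
    sys@illuminant <- full@illuminant
    sys
  } else if (name == "clinical_dual_lctf") {
    qe <- .qeFromAnchors(
      c(400, 460, 525, 580, 650, 750, 850, 950, 1000, 1100),
      c(0.45, 0.60, 0.72, 0.72, 0.65, 0.45, 0.25, 0.10, 0.06, 0.02))
    sys <- makeOpticalSystem(
      name = name,
      illuminant = .dualIlluminant(),
      passband = makePassband(c(460, 1000), fwhmNm = c(12, 24)),
      sensor = makeSensor(qe, bitDepth = 12, gain = 0.2, readNoiseRms = 0.5,
                          darkRateDnPerMs = 0.01, darkOffsetDn = 40),
      grid = makeGrid(460, 1000, 5, "closed"),
      throughput = 0.9,
      mode = "emission_filtering",
      transitionRangeNm = c(720, 740),
      transitionMagnitude = 1.15)
    .scaleSystemTo(sys, peakRateDnPerMs %||% 30)
  } else {
    # uneven anchors emulate the strong per-band sensitivity swings of a
    # column-filter mosaic sensor
    qe <- .qeFromAnchors(
      c(470, 520, 560, 600, 640, 700, 750, 800, 850, 900),
      c(0.25, 0.45, 0.28, 0.55, 0.20, 0.50, 0.30, 0.35, 0.18, 0.08))
    sys <- makeOpticalSystem(
      name = name,
      illuminant = makeIlluminant("halogen_broadband"),
      passband = makePassband(c(470, 900), fwhmNm = c(7, 7),
                              peakTransmission = 0.6),
      sensor = makeSensor(qe, bitDepth = 10, gain = 0.1, readNoiseRms = 1.5,
                          darkRateDnPerMs = 0.005, darkOffsetDn = 6),
      grid = makeGrid(470, 900, 5, "closed"),
      throughput = 1,
      mode = "reception_filtering")
    .scaleSystemTo(sys, peakRateDnPerMs %||% 3)
  }
}

#' Mean passband FWHM of a system over its grid
#'
#' @param system an [OpticalSystemModel-class].
#' @return mean FWHM in nm across the system's band centers.
#' @export
averageFwhm <- function(system) {
  mean(system@passband@fwhmFun(wavelengths(system@grid)))
}
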