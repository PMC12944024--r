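# White/dark reflectance calibration and min-max normalization.

#' Flat-field reflectance calibration
#'
#' `R = (raw - dark) / (white - dark)` per voxel and band. The white and
#' dark references may be full cubes of the same geometry or per-band mean
#' spectra (broadcast spatially). Voxels where the denominator is at or
#' below the stability threshold, or where the raw or white data are
#' saturated, are masked invalid (set to 0 with `invalidMask` TRUE) rather
#' than clipped; values slightly above 1 from noise are retained so error
#' statistics stay unbiased.
#'
#' @param raw an [HSCube-class].
#' @param white an [HSCube-class] or a DN [Spectrum-class] of per-band
#'   white means.
#' @param dark an [HSCube-class] or a DN [Spectrum-class] of per-band dark
#'   means.
#' @param epsilonDn stability threshold for `white - dark` (default 1 DN).
#' @return a [ReflectanceCube-class].
#' @examples
#' # raw = white gives reflectance 1 everywhere
#' @export
calibrateReflectance <- function(raw, white, dark, epsilonDn = 1) {
  stopifnot(is(raw, "HSCube"))
  .checkSameGrid(raw, white, "raw and white")
  .checkSameGrid(raw, dark, "raw and dark")
  d <- dim(raw@data)
  nb <- d[3]
  expand <- function(x, satDefault = FALSE) {
    if (is(x, "HSCube")) {
      if (!identical(dim(x@data)[1:2], d[1:2]))
        stop("reference cube geometry does not match the raw cube")
      list(data = x@data, sat = x@saturated)
    } else if (is(x, "Spectrum")) {
      a <- array(rep(x@values, each = d[1] * d[2]), dim = d)
      list(data = a, sat = array(satDefault, dim = d))
    } else stop("references must be HSCube or Spectrum")
  }
  w <- expand(white); dk <- expand(dark)
  denom <- w$data - dk$data
  invalid <- denom <= epsilonDn | raw@saturated | w$sat
  refl <- array(0, dim = d)
  ok <- !invalid
  refl[ok] <- (raw@data[ok] - dk$data[ok]) / denom[ok]
  # out-of-model voxels (e.g. raw below dark beyond plausible noise) are
  # kept; only non-finite results would violate the container contract
  refl[!is.finite(refl)] <- 0
  invalid <- invalid | !is.finite(denom)
  new("ReflectanceCube", data = refl, grid = raw@grid, invalidMask = invalid)
}

#' Min--max normalization of a spectrum
#'
#' `(x - min(x)) / (max(x) - min(x))`; the output attains 0 and 1 and is
#' invariant under positive affine transforms of the input. Constant
#' spectra have no defined scaling and raise an error.
#'
#' @param spectrum a [Spectrum-class] (any unit).
#' @return a [Spectrum-class] with unit `"ratio"`.
#' @examples
#' g <- makeGrid(500, 520, 10)
#' spectrumValues(minmaxNormalize(makeSpectrum(g, c(2, 4, 6), "dn")))
#' # 0 0.5 1
#' @export
minmaxNormalize <- function(spectrum) {
  stopifnot(is(spectrum, "Spectrum"))
  v <- spectrum@values
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant spectrum: min-max normalization is undefined")
  makeSpectrum(spectrum@grid, (v - rng[1]) / diff(rng), "ratio")
}
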