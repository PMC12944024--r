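# QC metric suite: spectral RMSE, dynamic range, SNR, OECF linearity,
# inter-band RMSE, and system comparison tables.

#' Spectral RMSE between a reference and a measured spectrum
#'
#' `sqrt(sum((y_i - yhat_i)^2) / N)` over the N shared bands, computed on
#' reflectance fractions and reported on the percent reflectance scale
#' (x100). When the grids differ and `resample = TRUE`, the reference is
#' linearly interpolated onto the measurement grid first.
#'
#' @param reference reference reflectance [Spectrum-class] (y).
#' @param measured measured reflectance [Spectrum-class] (yhat).
#' @param resample allow resampling the reference onto the measured grid.
#' @return RMSE in percent of the reflectance scale.
#' @examples
#' g <- makeGrid(500, 505, 5)
#' rmseSpectra(makeSpectrum(g, c(1, 0)), makeSpectrum(g, c(0, 1)))  # 100
#' @export
rmseSpectra <- function(reference, measured, resample = FALSE) {
  stopifnot(is(reference, "Spectrum"), is(measured, "Spectrum"))
  wr <- wavelengths(reference); wm <- wavelengths(measured)
  if (length(wr) != length(wm) || any(abs(wr - wm) > 1e-6)) {
    if (!resample)
      stop("spectra are on different grids (set resample = TRUE to interpolate the reference)")
    y <- stats::approx(wr, reference@values, xout = wm, rule = 2)$y
  } else y <- reference@values
  100 * sqrt(mean((y - measured@values)^2))
}

#' Per-band and global dynamic range in dB
#'
#' `DR = 20 * log10(W_r / D_r)` per band, where `W_r` and `D_r` are the
#' mean digital values of the brightest (95% reflectance) and darkest
#' grayscale elements. The global value is the unweighted mean over bands;
#' bands with a non-positive denominator are excluded from it with a
#' warning.
#'
#' @param whiteDn per-band mean DN of the bright element (W_r).
#' @param darkDn per-band mean DN of the dark element (D_r).
#' @return list with `perBandDb`, `globalDb`, `excluded` (band indices).
#' @examples
#' dynamicRange(1000, 10)$perBandDb  # 40
#' @export
dynamicRange <- function(whiteDn, darkDn) {
  stopifnot(length(whiteDn) == length(darkDn))
  bad <- darkDn <= 0 | whiteDn <= 0
  db <- rep(NA_real_, length(whiteDn))
  db[!bad] <- 20 * log10(whiteDn[!bad] / darkDn[!bad])
  if (any(bad))
    warning(sum(bad), " band(s) with non-positive level excluded from the global DR")
  list(perBandDb = db, globalDb = mean(db[!bad]), excluded = which(bad))
}

#' Per-band and global signal-to-noise ratio in dB
#'
#' `SNR = 20 * log10(mean(signal) / SD(noise))` per band; the signal is
#' the mean DN of the bright grayscale element and the noise the standard
#' deviation measured in the dark-current element. Global value and
#' exclusions as in [dynamicRange()].
#'
#' @param signalDn per-band mean signal DN.
#' @param noiseSd per-band noise standard deviation in DN.
#' @return list with `perBandDb`, `globalDb`, `excluded`.
#' @examples
#' snrDb(1000, 10)$perBandDb  # 40
#' @export
snrDb <- function(signalDn, noiseSd) {
  stopifnot(length(signalDn) == length(noiseSd))
  bad <- noiseSd <= 0 | signalDn <= 0
  db <- rep(NA_real_, length(signalDn))
  db[!bad] <- 20 * log10(signalDn[!bad] / noiseSd[!bad])
  if (any(bad))
    warning(sum(bad), " band(s) with zero noise SD excluded from the global SNR")
  list(perBandDb = db, globalDb = mean(db[!bad]), excluded = which(bad))
}

#' Opto-electronic conversion function and linearity deviation
#'
#' Builds the OECF point set: the status T density `D = -log10(nominal)`
#' of each grayscale tile paired with its mean measured reflectance, per
#' band. An ideal radiometrically linear system reproduces
#' `measured = 10^-D` (the identity in reflectance terms) and its points
#' fall on a straight line against the nominal reflectances; any error in
#' the quantification process shows up as a deviation. The reported
#' `deviation` is the maximum absolute residual from the least-squares
#' line of measured on nominal reflectance (a pure nonlinearity measure,
#' exactly 0 for an ideal or any affine response), with the fit R^2;
#' `identityDeviation` is the maximum absolute departure from the ideal
#' response itself, `max |measured - nominal|`.
#'
#' @param nominalReflectance nominal tile reflectances (>= 3 tiles).
#' @param measuredReflectance matrix of measured mean reflectances, one
#'   row per band and one column per tile (or a vector for a single band /
#'   band-averaged analysis).
#' @return list with `points` (data.frame tile, density, nominal,
#'   measured = band-averaged), `perBand` (data.frame band, deviation,
#'   r2), `deviation`, `r2` and `identityDeviation` of the band-averaged
#'   points.
#' @export
oecf <- function(nominalReflectance, measuredReflectance) {
  if (length(nominalReflectance) < 3)
    stop("OECF analysis needs at least 3 grayscale tiles")
  dens <- statusTDensity(nominalReflectance)
  m <- if (is.matrix(measuredReflectance)) measuredReflectance
       else matrix(measuredReflectance, nrow = 1)
  if (ncol(m) != length(nominalReflectance))
    stop("measured columns must match the number of tiles")
  fitDev <- function(y) {
    fit <- stats::lm.fit(cbind(1, nominalReflectance), y)
    res <- fit$residuals
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    c(deviation = max(abs(res)), r2 = r2)
  }
  perBand <- t(apply(m, 1, fitDev))
  avg <- colMeans(m)
  overall <- fitDev(avg)
  list(points = data.frame(tile = seq_along(dens), density = dens,
                           nominal = nominalReflectance, measured = avg),
       perBand = data.frame(band = seq_len(nrow(m)),
                            deviation = perBand[, "deviation"],
                            r2 = perBand[, "r2"]),
       deviation = unname(overall["deviation"]),
       r2 = unname(overall["r2"]),
       identityDeviation = max(abs(avg - nominalReflectance)))
}

#' Inter-band RMSE series of a cube
#'
#' For each band `i >= 2`, the RMSE over all pixels between band `i` and
#' band `i - 1`, on the percent reflectance scale -- elevated values
#' indicate motion or scanning artefacts. Voxels masked invalid in either
#' band are excluded.
#'
#' @param cube a [ReflectanceCube-class].
#' @return list with `perBandPct` (named by the wavelength of band `i`)
#'   and `meanPct`.
#' @export
interbandRmse <- function(cube) {
  stopifnot(is(cube, "ReflectanceCube"))
  nb <- nBands(cube)
  if (nb < 2) stop("inter-band RMSE needs at least 2 bands")
  wl <- wavelengths(cube)
  out <- vapply(seq(2, nb), function(b) {
    ok <- !(cube@invalidMask[, , b] | cube@invalidMask[, , b - 1])
    if (!any(ok)) return(NA_real_)
    d <- cube@data[, , b][ok] - cube@data[, , b - 1][ok]
    100 * sqrt(mean(d^2))
  }, numeric(1))
  names(out) <- wl[-1]
  list(perBandPct = out, meanPct = mean(out, na.rm = TRUE))
}

#' Characterize a system from simulated or loaded captures
#'
#' Runs the full QC suite on a grayscale-chart acquisition: calibrates the
#' raw cube, extracts per-tile ROI statistics, and computes dynamic range
#' (bright vs darkest grayscale element, on raw DN), SNR (bright-element
#' mean vs darkest-element SD, raw DN), the OECF with its linearity
#' deviation (on calibrated reflectance), the inter-band RMSE series
#' (calibrated reflectance), and -- when a reference standard measurement
#' is supplied -- the spectral RMSE. The darkest grayscale tile stands in
#' for the nominal "20% reflectance element" of the DR/SNR definitions;
#' this substitution is recorded in `meta$warnings`.
#'
#' @param raw raw chart [HSCube-class].
#' @param white,dark reference cubes or per-band DN spectra for
#'   calibration.
#' @param scene the [SceneTarget-class] the chart was captured from (for
#'   the tile layout and nominal reflectances).
#' @param system optional [OpticalSystemModel-class] for metadata (FWHM,
#'   name).
#' @param reference optional ground-truth reflectance [Spectrum-class] of
#'   a uniform standard.
#' @param measuredReference optional measured reflectance
#'   [Spectrum-class] of that standard.
#' @param roiSize tile ROI side length in pixels (default 10).
#' @return a [CharacterizationReport-class].
#' @export
characterizeSystem <- function(raw, white, dark, scene, system = NULL,
                               reference = NULL, measuredReference = NULL,
                               roiSize = 10) {
  stopifnot(is(raw, "HSCube"), is(scene, "SceneTarget"))
  warningsSeen <- character()
  grabber <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warningsSeen <<- c(warningsSeen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  gray <- scene@grayscaleNominal
  if (length(gray) < 3) stop("scene has no usable grayscale strip")
  refl <- calibrateReflectance(raw, white, dark)
  tileSize <- function(lab) min(roiSize, patchRoi(scene, lab)@size)
  roiStats <- function(cube, lab)
    extractRoiSpectrum(cube, patchRoi(scene, lab, tileSize(lab)))
  brightLab <- names(gray)[which.max(gray)]
  darkLab <- names(gray)[which.min(gray)]
  warningsSeen <- c(warningsSeen, sprintf(
    "darkest grayscale tile (%s, nominal %.2f) used as the dark element for DR/SNR",
    darkLab, min(gray)))
  bright <- roiStats(raw, brightLab)
  darkTile <- roiStats(raw, darkLab)
  dr <- grabber(dynamicRange(bright$mean@values, darkTile$mean@values))
  snr <- grabber(snrDb(bright$mean@values, darkTile$sd@values))
  measured <- vapply(names(gray), function(lab)
    roiStats(refl, lab)$mean@values, numeric(nBands(raw)))
  oc <- oecf(unname(gray), measured)
  ib <- interbandRmse(refl)
  rmse <- if (!is.null(reference) && !is.null(measuredReference))
    rmseSpectra(reference, measuredReference, resample = TRUE)
  else NA_real_
  wl <- wavelengths(raw)
  meta <- list(
    systemName = if (!is.null(system)) system@name else "unknown",
    bands = nBands(raw),
    rangeNm = range(wl),
    spatialPx = dim(raw@data)[1:2],
    bitDepth = raw@bitDepth,
    fwhmNm = if (!is.null(system)) averageFwhm(system) else NA_real_,
    maxDrBandNm = wl[which.max(dr$perBandDb)],
    maxSnrBandNm = wl[which.max(snr$perBandDb)],
    excluded = union(dr$excluded, snr$excluded),
    warnings = warningsSeen)
  new("CharacterizationReport",
      systemName = meta$systemName, rmsePct = rmse,
      drDb = dr$perBandDb, drGlobalDb = dr$globalDb,
      snrDb = snr$perBandDb, snrGlobalDb = snr$globalDb,
      oecf = oc, interbandPct = ib$perBandPct,
      interbandMeanPct = ib$meanPct, meta = meta)
}

#' Side-by-side comparison table of characterization reports
#'
#' @param reports list of >= 2 [CharacterizationReport-class] (a report
#'   compared with itself gives identical columns).
#' @return data.frame with one row per metric (spatial resolution,
#'   spectral range, band count, average FWHM, maximum DR, maximum SNR
#'   with the band where it occurs, global DR/SNR, mean inter-band RMSE)
#'   and one column per system.
#' @export
compareSystems <- function(reports) {
  if (length(reports) < 2) stop("need at least two reports to compare")
  col <- function(r) {
    m <- r@meta
    c(`Spatial resolution` = paste0(m$spatialPx[1], " x ", m$spatialPx[2], " px"),
      `Spectral range` = paste0(m$rangeNm[1], "-", m$rangeNm[2], " nm"),
      `Number of bands` = as.character(m$bands),
      `Average FWHM` = sprintf("%.3g nm", m$fwhmNm),
      `Bit depth` = as.character(m$bitDepth),
      `Maximum DR` = sprintf("%.3g dB (%g nm)",
                             max(r@drDb, na.rm = TRUE), m$maxDrBandNm),
      `Maximum SNR` = sprintf("%.3g dB (%g nm)",
                              max(r@snrDb, na.rm = TRUE), m$maxSnrBandNm),
      `Global DR` = sprintf("%.3g dB", r@drGlobalDb),
      `Global SNR` = sprintf("%.3g dB", r@snrGlobalDb),
      `Mean inter-band RMSE` = sprintf("%.3g %%", r@interbandMeanPct),
      `RMSE vs reference` = if (is.na(r@rmsePct)) "-" else
        sprintf("%.3g %%", r@rmsePct))
  }
  cols <- lapply(reports, col)
  names(cols) <- vapply(reports, function(r) r@systemName, character(1))
  out <- data.frame(metric = names(cols[[1]]), cols,
                    check.names = FALSE, row.names = NULL)
  out
}
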