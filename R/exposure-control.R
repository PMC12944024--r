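# Wavelength-dependent exposure control: characterize per-band efficiency
# from sparse white-reference captures, solve per-band exposure towards a
# target DN with a cap, densify to the acquisition grid with a
# shape-preserving spline, and budget total acquisition time.

#' Characterize per-band system efficiency from white captures
#'
#' Efficiency is the signal above dark per millisecond:
#' `(meanDn - darkLevel) / exposureMs` at each sampled wavelength.
#' Samples where the mean DN does not exceed the dark level are clamped to
#' zero efficiency with a warning (no measurable signal). The target DN of
#' the downstream solver is interpreted on the same above-dark scale, so
#' the solution is invariant to the dark level.
#'
#' @param whiteCaptures data.frame with columns `wavelengthNm`, `meanDn`,
#'   `exposureMs` (one row per characterization sample, typically every
#'   20 nm).
#' @param darkLevel dark DN level subtracted before the division.
#' @return an [EfficiencyCurve-class].
#' @examples
#' characterizeEfficiency(
#'   data.frame(wavelengthNm = 650, meanDn = 2550, exposureMs = 250),
#'   darkLevel = 50)  # 10 DN/ms
#' @export
characterizeEfficiency <- function(whiteCaptures, darkLevel) {
  if (!is.data.frame(whiteCaptures) || nrow(whiteCaptures) == 0)
    stop("whiteCaptures must be a non-empty data.frame")
  need <- c("wavelengthNm", "meanDn", "exposureMs")
  if (!all(need %in% names(whiteCaptures)))
    stop("whiteCaptures needs columns: ", paste(need, collapse = ", "))
  if (any(whiteCaptures$exposureMs <= 0)) stop("exposures must be > 0")
  o <- order(whiteCaptures$wavelengthNm)
  wc <- whiteCaptures[o, ]
  signal <- wc$meanDn - darkLevel
  if (any(signal <= 0)) {
    warning(sprintf("%d sample(s) at or below the dark level; efficiency clamped to 0",
                    sum(signal <= 0)))
    signal <- pmax(signal, 0)
  }
  new("EfficiencyCurve", wavelengthsNm = wc$wavelengthNm,
      dnPerMs = signal / wc$exposureMs,
      refExposureMs = wc$exposureMs[1])
}

# evaluate an efficiency curve at arbitrary wavelengths (linear between
# knots, nearest-knot beyond the span)
.effAt <- function(eff, wl) {
  if (length(eff@wavelengthsNm) == 1) return(rep(eff@dnPerMs, length(wl)))
  stats::approx(eff@wavelengthsNm, eff@dnPerMs, xout = wl, rule = 2)$y
}

# numeric stand-in for an infinite uncapped exposure at zero-efficiency
# bands, kept finite so spline densification stays well-posed
.boundUncapped <- function(tUnc, tMax) pmin(tUnc, 100 * tMax)

#' Solve per-band exposure towards a target digital number
#'
#' `t(lambda) = min(targetDn / efficiency(lambda), tMaxMs)`. Bands whose
#' uncapped solution exceeds the cap (including zero-efficiency bands,
#' which get the cap) are flagged as low-sensitivity. The target is the
#' signal above dark.
#'
#' @param eff an [EfficiencyCurve-class].
#' @param targetDn target digital number (above dark), > 0.
#' @param tMaxMs exposure cap in ms, > 0.
#' @param grid optional [SpectralGrid-class] to solve on; by default a
#'   closed grid through the efficiency knots (knots must then be equally
#'   spaced). Efficiency is interpolated linearly between knots.
#' @param strategy label stored on the profile (`"custom"` by default).
#' @param saturationDn optional sensor top code; a target at or above it is
#'   unreachable without saturation and raises an error.
#' @return an [ExposureProfile-class].
#' @examples
#' eff <- characterizeEfficiency(
#'   data.frame(wavelengthNm = c(650, 670), meanDn = c(5050, 5050),
#'              exposureMs = 250), darkLevel = 50)
#' exposureTimes(solveExposure(eff, 3000, 500))  # 150 150
#' @export
solveExposure <- function(eff, targetDn, tMaxMs, grid = NULL,
                          strategy = "custom", saturationDn = NULL) {
  stopifnot(is(eff, "EfficiencyCurve"), targetDn > 0, tMaxMs > 0)
  if (!is.null(saturationDn) && targetDn >= saturationDn)
    stop(sprintf("target %g DN is not reachable without saturation (top code %g)",
                 targetDn, saturationDn))
  if (is.null(grid)) {
    k <- eff@wavelengthsNm
    if (length(k) < 2) stop("need a grid or at least two efficiency knots")
    steps <- diff(k)
    if (any(abs(steps - steps[1]) > 1e-6))
      stop("efficiency knots are unequally spaced; supply 'grid' explicitly")
    grid <- makeGrid(min(k), max(k), steps[1], "closed")
  }
  wl <- wavelengths(grid)
  e <- .effAt(eff, wl)
  tUnc <- ifelse(e > 0, targetDn / e, Inf)
  flagged <- tUnc > tMaxMs
  new("ExposureProfile", grid = grid, tMs = pmin(tUnc, tMaxMs),
      tUncappedMs = .boundUncapped(tUnc, tMaxMs),
      targetDn = targetDn, tMaxMs = tMaxMs, strategy = strategy,
      lowSensitivity = flagged)
}

#' Constant exposure profile
#'
#' @param grid a [SpectralGrid-class].
#' @param tMs the constant exposure in ms.
#' @param targetDn nominal target recorded on the profile (default `NA`).
#' @return an [ExposureProfile-class] with strategy `"constant"`.
#' @export
constantProfile <- function(grid, tMs, targetDn = NA_real_) {
  nb <- length(wavelengths(grid))
  new("ExposureProfile", grid = grid, tMs = rep(tMs, nb),
      tUncappedMs = rep(tMs, nb), targetDn = targetDn, tMaxMs = tMs,
      strategy = "constant", lowSensitivity = rep(FALSE, nb))
}

#' Densify a sparse exposure profile to a finer grid
#'
#' Interpolates the *uncapped* per-band solution from the characterization
#' knots onto the target grid with a shape-preserving monotone cubic
#' Hermite spline (PCHIP), which passes through the knots exactly and
#' cannot overshoot beyond neighboring knot values (a natural cubic spline
#' can, which would silently break the exposure cap between knots). The
#' cap is re-applied after interpolation and low-sensitivity flags are
#' recomputed. Beyond the outermost knots the nearest knot value is held.
#'
#' @param profile a sparse [ExposureProfile-class] (>= 2 bands).
#' @param grid the target [SpectralGrid-class] (e.g. the 5 nm acquisition
#'   grid).
#' @return a dense [ExposureProfile-class].
#' @export
densifyProfile <- function(profile, grid) {
  stopifnot(is(profile, "ExposureProfile"), is(grid, "SpectralGrid"))
  knotsX <- wavelengths(profile)
  if (length(knotsX) < 2) stop("need at least two knots to densify")
  wl <- wavelengths(grid)
  wlClamped <- pmin(pmax(wl, min(knotsX)), max(knotsX))
  tUnc <- pracma::pchip(knotsX, profile@tUncappedMs, wlClamped)
  flagged <- tUnc > profile@tMaxMs
  new("ExposureProfile", grid = grid, tMs = pmin(tUnc, profile@tMaxMs),
      tUncappedMs = .boundUncapped(tUnc, profile@tMaxMs),
      targetDn = profile@targetDn, tMaxMs = profile@tMaxMs,
      strategy = profile@strategy, lowSensitivity = flagged)
}

#' @describeIn totalAcquisitionTime for an exposure profile
#' @export
setMethod("totalAcquisitionTime", "ExposureProfile",
  function(profile, overheadMs = 0) {
    stopifnot(overheadMs >= 0)
    (sum(profile@tMs) + length(profile@tMs) * overheadMs) / 1000
  })

#' @describeIn totalAcquisitionTime for a bare vector of per-band
#'   exposures in ms (an empty vector gives 0 s)
#' @export
setMethod("totalAcquisitionTime", "numeric",
  function(profile, overheadMs = 0) {
    stopifnot(overheadMs >= 0)
    (sum(profile) + length(profile) * overheadMs) / 1000
  })

# mean DN of a simulated uniform capture at one band (cheap primitive used
# for characterization sweeps; full-frame statistics without building a cube)
.simulateFlatMeanDn <- function(system, bandNm, reflectance, exposureMs,
                                nPix, noise = TRUE) {
  sn <- system@sensor
  rate <- bandSignalRate(system, bandNm)
  sig <- rate * exposureMs * reflectance
  dark <- sn@darkOffsetDn + sn@darkRateDnPerMs * exposureMs
  if (!noise) return(min(max(dark + sig, 0), 2^sn@bitDepth - 1))
  dn <- dark + stats::rpois(nPix, sig / sn@gain) * sn@gain +
    stats::rnorm(nPix, 0, sn@readNoiseRms)
  mean(pmin(pmax(round(dn), 0), 2^sn@bitDepth - 1))
}

#' Simulate a sparse white-reference characterization sweep
#'
#' Captures a white reference (reflectance 1) at each sample wavelength at
#' a common reference exposure and returns the per-sample mean DN over a
#' uniform region -- the input [characterizeEfficiency()] expects.
#'
#' @param system an [OpticalSystemModel-class].
#' @param sampleNm sample wavelengths (e.g. every 20 nm).
#' @param refExposureMs common reference exposure in ms.
#' @param nPix pixels averaged per sample.
#' @param noise simulate noise (`TRUE`) or return expected values.
#' @param seed optional integer seed.
#' @return data.frame with `wavelengthNm`, `meanDn`, `exposureMs`.
#' @export
simulateWhiteCaptures <- function(system, sampleNm, refExposureMs,
                                  nPix = 1024, noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    wavelengthNm = sampleNm,
    meanDn = vapply(sampleNm, function(l)
      .simulateFlatMeanDn(system, l, 1, refExposureMs, nPix, noise),
      numeric(1)),
    exposureMs = refExposureMs)
}

# built-in strategy definitions for the trade-off experiment
.strategyDefs <- function(targetDn, constantMs) list(
  constant = list(strategy = "constant", tMs = constantMs),
  short_limit = list(strategy = "short_limit", targetDn = targetDn, tMaxMs = 500),
  long_limit = list(strategy = "long_limit", targetDn = targetDn, tMaxMs = 1200))

#' Serialize an exposure profile as two-column text plus metadata
#'
#' Writes `<path>` as tab-separated `wavelengthNm` / `exposureMs` and
#' `<path>.meta.json` with the target DN, cap, strategy, grid convention
#' and low-sensitivity flags.
#'
#' @param profile an [ExposureProfile-class].
#' @param path output text-file path.
#' @return `path`, invisibly.
#' @seealso [readExposureProfile()]
#' @export
writeExposureProfile <- function(profile, path) {
  utils::write.table(
    data.frame(wavelengthNm = wavelengths(profile),
               exposureMs = profile@tMs),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  g <- profile@grid
  jsonlite::write_json(
    list(targetDn = profile@targetDn, tMaxMs = profile@tMaxMs,
         strategy = profile@strategy,
         tUncappedMs = profile@tUncappedMs,
         lowSensitivity = profile@lowSensitivity,
         grid = list(startNm = g@startNm, endNm = g@endNm, stepNm = g@stepNm,
                     convention = g@convention)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read an exposure profile written by [writeExposureProfile()]
#'
#' @param path text-file path (the `.meta.json` sidecar must sit next to it).
#' @return an [ExposureProfile-class].
#' @export
readExposureProfile <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  grid <- makeGrid(meta$grid$startNm, meta$grid$endNm, meta$grid$stepNm,
                   meta$grid$convention)
  if (any(abs(wavelengths(grid) - tab$wavelengthNm) > 1e-6))
    stop("profile wavelengths do not match the sidecar grid")
  new("ExposureProfile", grid = grid, tMs = tab$exposureMs,
      tUncappedMs = as.numeric(meta$tUncappedMs),
      targetDn = as.numeric(meta$targetDn %||% NA_real_),
      tMaxMs = meta$tMaxMs,
      strategy = meta$strategy,
      lowSensitivity = as.logical(meta$lowSensitivity))
}

#' RMSE-versus-acquisition-time trade-off across exposure strategies
#'
#' For each strategy: characterize the system efficiency from sparse
#' (20 nm) white captures, solve and densify the exposure profile, simulate
#' white, dark and reference-target captures, calibrate, and compute the
#' spectral RMSE of the recovered spectrum against the scene ground truth,
#' paired with the total acquisition time.
#'
#' @param system an [OpticalSystemModel-class].
#' @param reference ground-truth reflectance [Spectrum-class] on the
#'   system grid (e.g. from [makeZenithLikeReference()]).
#' @param strategies character subset of
#'   `c("constant", "short_limit", "long_limit")`.
#' @param seed integer seed driving all stochastic stages.
#' @param targetDn solver target for the variable strategies (above dark).
#' @param constantMs exposure of the constant strategy, ms.
#' @param characterizationStrideNm spacing of the characterization sweep.
#' @param refExposureMs reference exposure of the sweep.
#' @param framePx simulated frame side length in pixels.
#' @param nRepeats independent acquisition repeats per strategy; the
#'   reported RMSE is the root mean of the squared per-repeat RMSEs, which
#'   stabilizes the estimate (a single acquisition's RMSE carries large
#'   sampling noise because each band contributes one noise draw).
#' @param noise simulate noise (`TRUE`) or run the noiseless limit.
#' @return data.frame with columns `strategy`, `totalTimeS`, `rmsePct`.
#' @export
exposureTradeoffCurve <- function(system, reference,
                                  strategies = c("constant", "short_limit",
                                                 "long_limit"),
                                  seed = 1, targetDn = 800, constantMs = 250,
                                  characterizationStrideNm = 20,
                                  refExposureMs = 100, framePx = 16,
                                  nRepeats = 6, noise = TRUE) {
  stopifnot(is(reference, "Spectrum"))
  grid <- reference@grid
  defs <- .strategyDefs(targetDn, constantMs)
  strategies <- match.arg(strategies, names(defs), several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  wl <- wavelengths(grid)
  sampleNm <- seq(min(wl), max(wl), by = characterizationStrideNm)
  dark <- system@sensor@darkOffsetDn +
    system@sensor@darkRateDnPerMs * refExposureMs
  sweep <- simulateWhiteCaptures(system, sampleNm, refExposureMs,
                                 nPix = 4096, noise = noise)
  eff <- characterizeEfficiency(sweep, darkLevel = dark)
  scene <- makeFlatScene(grid, reference, nrow = framePx, ncol = framePx)
  whiteScene <- makeFlatScene(grid, 1, nrow = framePx, ncol = framePx)
  darkScene <- makeFlatScene(grid, 0, nrow = framePx, ncol = framePx)
  out <- lapply(strategies, function(s) {
    d <- defs[[s]]
    profile <- if (s == "constant") constantProfile(grid, d$tMs)
    else {
      knotGrid <- makeGrid(min(sampleNm), max(sampleNm),
                           characterizationStrideNm, "closed")
      sparse <- solveExposure(eff, d$targetDn, d$tMaxMs, grid = knotGrid,
                              strategy = d$strategy,
                              saturationDn = 2^system@sensor@bitDepth - 1)
      densifyProfile(sparse, grid)
    }
    rmseSq <- vapply(seq_len(if (noise) nRepeats else 1L), function(i) {
      raw <- simulateCube(scene, system, profile, noise = noise)
      white <- simulateCube(whiteScene, system, profile, noise = noise)
      darkCube <- simulateCube(darkScene, system, profile, noise = noise)
      refl <- calibrateReflectance(raw, white, darkCube)
      measured <- extractRoiSpectrum(refl,
        makeRoi(framePx %/% 2L, framePx %/% 2L, framePx))$mean
      rmseSpectra(reference, measured)^2
    }, numeric(1))
    data.frame(strategy = s,
               totalTimeS = totalAcquisitionTime(profile),
               rmsePct = sqrt(mean(rmseSq)))
  })
  do.call(rbind, out)
}

#' Relative RMSE reduction and time efficiency of exposure strategies
#'
#' Summarizes a trade-off curve against a baseline strategy: the relative
#' RMSE reduction `100 * (rmse_base - rmse) / rmse_base` (percent) and its
#' normalization by the additional acquisition time (percentage points of
#' reduction per extra second).
#'
#' @param curve data.frame with `strategy`, `totalTimeS`, `rmsePct` (as
#'   returned by [exposureTradeoffCurve()], or assembled from measured
#'   values).
#' @param baseline strategy name used as the reference (default
#'   `"constant"`).
#' @return data.frame with `strategy`, `totalTimeS`, `rmsePct`,
#'   `reductionPct`, `extraTimeS`, `reductionPctPerS` (NA for the baseline).
#' @examples
#' tradeoffSummary(data.frame(
#'   strategy = c("constant", "short_limit", "long_limit"),
#'   totalTimeS = c(28, 32, 50), rmsePct = c(26, 12, 5)))
#' @export
tradeoffSummary <- function(curve, baseline = "constant") {
  stopifnot(baseline %in% curve$strategy)
  b <- curve[curve$strategy == baseline, ]
  curve$reductionPct <- 100 * (b$rmsePct - curve$rmsePct) / b$rmsePct
  curve$extraTimeS <- curve$totalTimeS - b$totalTimeS
  curve$reductionPctPerS <- ifelse(curve$extraTimeS > 0,
                                   curve$reductionPct / curve$extraTimeS, NA)
  curve
}
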