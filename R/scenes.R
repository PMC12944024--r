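# Built-in reference-target scene generators.

#' Status T density of a reflectance
#'
#' Photographic density `-log10(reflectance)` of a calibrated grayscale
#' tile, the abscissa of the OECF plot.
#'
#' @param reflectance reflectance fraction in (0, 1].
#' @return density (unitless).
#' @examples
#' statusTDensity(0.95)  # ~0.0223
#' @export
statusTDensity <- function(reflectance) {
  stopifnot(all(reflectance > 0))
  -log10(reflectance)
}

#' Uniform (flat) scene
#'
#' A scene with no patches whose background carries the given spectrum --
#' used for white references (reflectance 1), dark references
#' (reflectance 0), and uniform reflectance standards.
#'
#' @param grid a [SpectralGrid-class].
#' @param reflectance a scalar, a per-band vector, or a [Spectrum-class].
#' @param nrow,ncol scene size in pixels.
#' @return a [SceneTarget-class].
#' @export
makeFlatScene <- function(grid, reflectance, nrow = 32, ncol = 32) {
  vals <- if (is(reflectance, "Spectrum")) reflectance@values
          else rep_len(reflectance, length(wavelengths(grid)))
  new("SceneTarget", nrow = as.integer(nrow), ncol = as.integer(ncol),
      grid = grid,
      patches = data.frame(label = character(), row1 = integer(),
                           row2 = integer(), col1 = integer(),
                           col2 = integer(), stringsAsFactors = FALSE),
      spectra = list(),
      background = makeSpectrum(grid, vals, "reflectance"),
      grayscaleNominal = numeric())
}

#' Color-checker style test chart with a 12-step grayscale
#'
#' Generates a synthetic stand-in for a calibrated resolution/color test
#' chart: a 6 x 7 matrix of color patches with flat or gently sloped
#' reflectance spectra, and a 12-tile grayscale strip with nominal
#' reflectances stepping from 0.95 (tile G1) down to 0.24 (tile G12).
#' Patch spectra are deterministic functions of the patch position, so the
#' scene needs no seed.
#'
#' @param grid a [SpectralGrid-class].
#' @param patchPx color-patch side length in pixels.
#' @param gapPx gap between patches in pixels.
#' @return a [SceneTarget-class]; grayscale tiles are labelled
#'   `"G1"`..`"G12"`, color patches `"C<row>_<col>"`.
#' @export
makeRezCheckerScene <- function(grid, patchPx = 14, gapPx = 4) {
  wl <- wavelengths(grid)
  patchPx <- as.integer(patchPx); gapPx <- as.integer(gapPx)
  mid <- mean(range(wl)); span <- diff(range(wl))
  nGray <- 12L
  grayNominal <- round(seq(0.95, 0.24, length.out = nGray), 4)
  names(grayNominal) <- paste0("G", seq_len(nGray))
  grayPx <- max(6L, patchPx %/% 2L + 2L)

  colorW <- 7L * (patchPx + gapPx) + gapPx
  grayW <- nGray * (grayPx + 2L) + 2L
  ncol <- max(colorW, grayW)
  nrow <- 6L * (patchPx + gapPx) + gapPx + grayPx + 2L * gapPx

  labs <- character(); r1 <- r2 <- c1 <- c2 <- integer()
  spectra <- list()
  for (i in 1:6) for (j in 1:7) {
    lab <- sprintf("C%d_%d", i, j)
    top <- gapPx + (i - 1L) * (patchPx + gapPx) + 1L
    left <- gapPx + (j - 1L) * (patchPx + gapPx) + 1L
    labs <- c(labs, lab)
    r1 <- c(r1, top); r2 <- c(r2, top + patchPx - 1L)
    c1 <- c(c1, left); c2 <- c(c2, left + patchPx - 1L)
    k <- (i - 1L) * 7L + j
    level <- 0.15 + 0.6 * ((k * 5L) %% 9L) / 9
    slope <- c(-0.25, 0, 0.25)[(k %% 3L) + 1L]
    spectra[[lab]] <- makeSpectrum(
      grid, pmin(pmax(level + slope * (wl - mid) / span, 0.05), 0.95))
  }
  grayTop <- 6L * (patchPx + gapPx) + 2L * gapPx + 1L
  for (k in seq_len(nGray)) {
    lab <- names(grayNominal)[k]
    left <- 2L + (k - 1L) * (grayPx + 2L) + 1L
    labs <- c(labs, lab)
    r1 <- c(r1, grayTop); r2 <- c(r2, grayTop + grayPx - 1L)
    c1 <- c(c1, left); c2 <- c(c2, left + grayPx - 1L)
    spectra[[lab]] <- makeSpectrum(grid, rep(grayNominal[[k]], length(wl)))
  }
  new("SceneTarget", nrow = nrow, ncol = as.integer(ncol), grid = grid,
      patches = data.frame(label = labs, row1 = r1, row2 = r2,
                           col1 = c1, col2 = c2, stringsAsFactors = FALSE),
      spectra = spectra,
      background = makeSpectrum(grid, rep(0.05, length(wl))),
      grayscaleNominal = grayNominal)
}

#' Center ROI of a labelled scene patch
#'
#' @param scene a [SceneTarget-class].
#' @param label patch label (e.g. `"G1"`).
#' @param size ROI side length in pixels; defaults to the largest square
#'   that fits the patch.
#' @return a [RegionOfInterest-class] at the patch center.
#' @export
patchRoi <- function(scene, label, size = NULL) {
  p <- scene@patches[scene@patches$label == label, ]
  if (!nrow(p)) stop("no patch labelled '", label, "'")
  if (is.null(size)) size <- min(p$row2 - p$row1, p$col2 - p$col1) + 1L
  makeRoi((p$row1 + p$row2) %/% 2L, (p$col1 + p$col2) %/% 2L, size)
}

#' Wavelength-standard reference spectrum with narrow absorption dips
#'
#' Generates a smooth synthetic stand-in for a rare-earth-doped diffuse
#' reflectance standard: a gently sloped baseline around 0.9 with `nDips`
#' narrow Gaussian absorption dips at seeded positions. The true dip
#' positions, depths and widths are returned as ground truth so recovery
#' can be tested (e.g. that convolving with a filter passband reduces the
#' apparent dip depth).
#'
#' @param grid a [SpectralGrid-class].
#' @param seed integer seed for the dip placement; `NULL` uses evenly
#'   spaced deterministic dips.
#' @param nDips number of absorption dips (>= 1).
#' @return list with `spectrum` (a reflectance [Spectrum-class]) and
#'   `dips` (data.frame: centerNm, depth, sigmaNm).
#' @export
makeZenithLikeReference <- function(grid, seed = NULL, nDips = 4) {
  wl <- wavelengths(grid)
  lo <- min(wl) + 0.08 * diff(range(wl))
  hi <- max(wl) - 0.08 * diff(range(wl))
  if (is.null(seed)) {
    centers <- seq(lo, hi, length.out = nDips)
    depths <- rep_len(c(0.3, 0.2, 0.35, 0.25), nDips)
    sigmas <- rep_len(c(6, 8, 5, 7), nDips)
  } else {
    set.seed(seed)
    # rejection placement keeps dips separated so they stay resolvable
    centers <- numeric()
    while (length(centers) < nDips) {
      cand <- stats::runif(1, lo, hi)
      if (!length(centers) || min(abs(centers - cand)) > 0.12 * diff(range(wl)))
        centers <- c(centers, cand)
    }
    centers <- sort(centers)
    depths <- stats::runif(nDips, 0.15, 0.35)
    sigmas <- stats::runif(nDips, 5, 9)
  }
  mid <- mean(range(wl))
  base <- 0.9 - 0.04 * (wl - mid) / diff(range(wl)) -
    0.03 * ((wl - mid) / diff(range(wl)))^2
  v <- base
  for (k in seq_len(nDips))
    v <- v - depths[k] * exp(-(wl - centers[k])^2 / (2 * sigmas[k]^2))
  v <- pmin(pmax(v, 0.02), 0.98)
  list(spectrum = makeSpectrum(grid, v, "reflectance"),
       dips = data.frame(centerNm = centers, depth = depths, sigmaNm = sigmas))
}
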