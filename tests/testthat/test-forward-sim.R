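# Radiometric model, noise realism, scene generators, scanning modes.

test_that("expected DN is affine in exposure and reflectance below saturation", {
  g <- tinyGrid()
  sys <- idealSystem(g, qe = 0.5, width = 10, gain = 0.1,
                     darkOffsetDn = 20, darkRateDnPerMs = 0.1)
  dark <- function(t) 20 + 0.1 * t
  # R = 0: dark only
  expect_equal(expectedDn(sys, 520, 0, 100), dark(100))
  # linear in t: doubling t doubles DN - dark
  s1 <- expectedDn(sys, 520, 0.4, 100) - dark(100)
  s2 <- expectedDn(sys, 520, 0.4, 200) - dark(200)
  expect_equal(s2, 2 * s1)
  # linear in R on a grid of reflectances
  r <- seq(0.1, 0.9, by = 0.2)
  sig <- expectedDn(sys, 520, r, 50) - dark(50)
  expect_equal(sig, r / 0.1 * sig[1])
  # clipping at the top code
  expect_equal(expectedDn(sys, 520, 1, 1e7), 2^12 - 1)
})

test_that("rectangular passband signal matches the closed form", {
  g <- tinyGrid()
  sys <- idealSystem(g, qe = 0.5, width = 10, gain = 0.1, throughput = 0.8)
  # signal = gain * throughput * t * width * qe * R
  closed <- 0.1 * 0.8 * 200 * 10 * 0.5 * 0.6
  sim <- expectedDn(sys, 520, 0.6, 200)
  expect_lt(abs(sim - closed) / closed, 1e-3)
})

test_that("an 87.5% throughput deficit needs 8x the exposure for equal signal", {
  efs <- systemPreset("nir_lab_efs")
  rfs <- systemPreset("nir_lab_rfs")
  sigAt <- function(sys, t) expectedDn(sys, 700, 1, t) -
    sys@sensor@darkOffsetDn - sys@sensor@darkRateDnPerMs * t
  expect_equal(sigAt(rfs, 2000), sigAt(efs, 250), tolerance = 1e-9)
  # and conversely the 250 -> 2000 ms pair implies 87.5% less light
  expect_equal(1 - bandSignalRate(rfs, 700) / bandSignalRate(efs, 700), 0.875)
})

test_that("noiseless simulation equals the rounded expected-DN map", {
  g <- tinyGrid()
  sys <- idealSystem(g, darkOffsetDn = 15, darkRateDnPerMs = 0.05)
  scene <- makeFlatScene(g, 0.37, 6, 6)
  cube <- simulateCube(scene, sys, constantProfile(g, 80), noise = FALSE)
  for (b in c(1, 3, 5))
    expect_true(all(cubeData(cube)[, , b] ==
                      round(expectedDn(sys, wavelengths(g)[b], 0.37, 80))))
})

test_that("simulation is deterministic under a seed", {
  g <- tinyGrid()
  sys <- idealSystem(g, readNoiseRms = 1, darkOffsetDn = 10)
  scene <- makeFlatScene(g, 0.5, 8, 8)
  p <- constantProfile(g, 50)
  expect_identical(cubeData(simulateCube(scene, sys, p, seed = 42)),
                   cubeData(simulateCube(scene, sys, p, seed = 42)))
  m <- makeMotionModel(2, schedule = "random_walk")
  expect_identical(
    cubeData(simulateSpatioScanCube(scene, sys, p, m, seed = 42)),
    cubeData(simulateSpatioScanCube(scene, sys, p, m, seed = 42)))
})

test_that("simulated noise matches the model mean and variance", {
  g <- tinyGrid()
  sys <- idealSystem(g, qe = 0.5, gain = 0.25, readNoiseRms = 2,
                     darkOffsetDn = 30, darkRateDnPerMs = 0.02)
  scene <- makeFlatScene(g, 0.5, 50, 50)
  t <- 120
  cube <- simulateCube(scene, sys, constantProfile(g, t), seed = 99)
  b <- 3
  mu <- expectedDn(sys, wavelengths(g)[b], 0.5, t)
  sig <- mu - 30 - 0.02 * t
  vModel <- 0.25 * sig + 2^2 + 1 / 12  # shot + read + quantization
  px <- as.vector(cubeData(cube)[, , b])
  se <- sqrt(vModel / length(px))
  expect_lt(abs(mean(px) - mu), 3 * se)
  # variance within the chi-square-ish envelope for n = 2500
  expect_gt(var(px) / vModel, 0.85)
  expect_lt(var(px) / vModel, 1.15)
})

test_that("grid mismatch between scene and profile is rejected", {
  sys <- idealSystem()
  scene <- makeFlatScene(tinyGrid(), 0.5, 4, 4)
  p <- constantProfile(makeGrid(500, 550, 10), 50)
  expect_error(simulateCube(scene, sys, p), "grid")
})

test_that("the grayscale chart generator matches its nominal layout", {
  scene <- makeRezCheckerScene(tinyGrid())
  labs <- scene@patches$label
  expect_equal(sum(grepl("^C", labs)), 42)  # 6 x 7 color matrix
  expect_equal(sum(grepl("^G", labs)), 12)
  expect_equal(unname(scene@grayscaleNominal[c("G1", "G12")]), c(0.95, 0.24))
  expect_equal(statusTDensity(0.95), 0.02227639, tolerance = 1e-6)
  expect_true(validObject(scene))  # non-overlap enforced by validity
  # every spectrum stays a reflectance fraction
  for (s in scene@spectra)
    expect_true(all(spectrumValues(s) >= 0 & spectrumValues(s) <= 1))
})

test_that("wavelength-standard generator returns recoverable ground truth", {
  g <- makeGrid(460, 1000, 5)
  zen <- makeZenithLikeReference(g, seed = 12)
  v <- spectrumValues(zen$spectrum)
  expect_true(all(v >= 0 & v <= 1))
  wl <- wavelengths(g)
  # each true dip is recovered as a local minimum near its center
  for (k in seq_len(nrow(zen$dips))) {
    cen <- zen$dips$centerNm[k]
    win <- abs(wl - cen) <= 15
    local <- which(win)[which.min(v[win])]
    expect_lt(abs(wl[local] - cen), 2 * g@stepNm + 1e-9)
  }
  # smoothing with an 18 nm FWHM Gaussian reduces every dip depth
  sigma <- 18 / (2 * sqrt(2 * log(2)))
  kern <- dnorm(seq(-40, 40, by = 5), sd = sigma)
  kern <- kern / sum(kern)
  sm <- stats::filter(v, kern, sides = 2)
  depth <- function(x, cen) {
    win <- abs(wl - cen) <= 12
    base <- max(x[win], na.rm = TRUE)
    base - min(x[win], na.rm = TRUE)
  }
  for (k in seq_len(nrow(zen$dips))) {
    cen <- zen$dips$centerNm[k]
    expect_lt(depth(as.numeric(sm), cen), depth(v, cen))
  }
})

test_that("spatio-spectral scan with zero motion equals the spectral scan", {
  g <- tinyGrid()
  sys <- idealSystem(g, darkOffsetDn = 10)
  scene <- makeRezCheckerScene(g, patchPx = 6, gapPx = 2)
  p <- constantProfile(g, 60)
  a <- simulateCube(scene, sys, p, noise = FALSE)
  b <- simulateSpatioScanCube(scene, sys, p, makeMotionModel(0), noise = FALSE)
  expect_identical(cubeData(a), cubeData(b))
})

test_that("constant inter-frame shift displaces a step edge between bands", {
  g <- tinyGrid()
  sys <- idealSystem(g, qe = 0.8, gain = 0.05)
  # one bright patch with a sharp horizontal edge
  grid <- g
  scene <- makeFlatScene(grid, 0.05, 24, 24)
  scene@patches <- data.frame(label = "P", row1 = 5L, row2 = 12L,
                              col1 = 3L, col2 = 22L)
  scene@spectra <- list(P = makeSpectrum(grid, rep(0.9, 5)))
  m <- makeMotionModel(3, schedule = "constant")
  cube <- simulateSpatioScanCube(scene, sys, constantProfile(grid, 100), m,
                                 noise = FALSE)
  # a constant downward shift of 3 px moves the bright edge 3 rows down
  # relative to the static acquisition, in every band and column
  static <- simulateCube(scene, sys, constantProfile(grid, 100), noise = FALSE)
  for (b in c(1, 5)) for (col in c(5, 15)) {
    moved <- which.max(diff(cubeData(cube)[, col, b]))
    fixed <- which.max(diff(cubeData(static)[, col, b]))
    expect_equal(moved, fixed + 3)
  }
})

test_that("inter-band error grows strictly with motion amplitude", {
  set.seed(23)
  g <- makeGrid(500, 590, 10)
  sys <- idealSystem(g, qe = 0.6, gain = 0.1, readNoiseRms = 0.5,
                     darkOffsetDn = 10)
  scene <- makeRezCheckerScene(g, patchPx = 6, gapPx = 2)
  p <- constantProfile(g, 100)
  white <- simulateCube(makeFlatScene(g, 1, scene@nrow, scene@ncol), sys, p)
  dark <- simulateCube(makeFlatScene(g, 0, scene@nrow, scene@ncol), sys, p)
  ib <- vapply(c(0, 1, 2, 4), function(a) {
    cube <- simulateSpatioScanCube(scene, sys, p, makeMotionModel(a))
    interbandRmse(calibrateReflectance(cube, white, dark))$meanPct
  }, numeric(1))
  expect_true(all(diff(ib) > 0))
})

test_that("filter-transition injection is local and magnitude-1 is identity", {
  g <- makeGrid(700, 760, 5)
  cube <- tinyCube(grid = g, bitDepth = 12, fill = 1000L)
  same <- injectFilterTransition(cube, c(720, 740), 1)
  expect_identical(cubeData(same), cubeData(cube))
  expect_equal(artefactBands(same), which(wavelengths(g) >= 720 &
                                          wavelengths(g) <= 740))
  up <- injectFilterTransition(cube, c(720, 740), 1.2)
  wl <- wavelengths(g)
  inside <- wl >= 720 & wl <= 740
  expect_true(all(cubeData(up)[, , inside] == 1200))
  expect_true(all(cubeData(up)[, , !inside] == 1000))
  expect_error(injectFilterTransition(cube, c(900, 950), 1.2), "no band")
})

test_that("a calibrated flat target shows the transition bump only in flagged bands", {
  g <- makeGrid(700, 760, 5)
  # signal sized well above the quantization step so the bump is clean
  sys <- idealSystem(g, qe = 0.6, gain = 0.5, darkOffsetDn = 10)
  p <- constantProfile(g, 400)
  raw <- simulateCube(makeFlatScene(g, 0.5, 10, 10), sys, p, noise = FALSE)
  raw <- injectFilterTransition(raw, c(720, 740), 1.2)
  white <- simulateCube(makeFlatScene(g, 1, 10, 10), sys, p, noise = FALSE)
  dark <- simulateCube(makeFlatScene(g, 0, 10, 10), sys, p, noise = FALSE)
  m <- extractRoiSpectrum(calibrateReflectance(raw, white, dark),
                          makeRoi(5, 5, 10))$mean
  flagged <- artefactBands(raw)
  v <- spectrumValues(m)
  expect_true(all(abs(v[flagged] - 0.6) < 0.01))   # 1.2 x 0.5 bump
  expect_true(all(abs(v[-flagged] - 0.5) < 0.01))  # flat elsewhere
})

test_that("the clinical preset perturbs and flags the 720-740 nm hand-over", {
  set.seed(77)
  sys <- systemPreset("clinical_dual_lctf")
  g <- sys@grid
  p <- constantProfile(g, 60)
  raw <- simulateCube(makeFlatScene(g, 0.5, 12, 12), sys, p)
  flagged <- artefactBands(raw)
  expect_equal(wavelengths(g)[flagged], seq(720, 740, by = 5))
  clean <- sys; clean@transitionMagnitude <- 1
  for (b in flagged) {
    mu <- expectedDn(clean, wavelengths(g)[b], 0.5, 60)
    expect_gt(mean(cubeData(raw)[, , b]) / mu, 1.01)
  }
})
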