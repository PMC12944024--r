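# QC metrics: spectral RMSE, DR/SNR closed forms, OECF, inter-band RMSE,
# comparison tables.

test_that("spectral RMSE matches hand-computed vectors", {
  g2 <- makeGrid(500, 505, 5)
  expect_equal(rmseSpectra(makeSpectrum(g2, c(1, 0)),
                           makeSpectrum(g2, c(1, 0))), 0)
  expect_equal(rmseSpectra(makeSpectrum(g2, c(1, 0)),
                           makeSpectrum(g2, c(0, 1))), 100)
  g <- tinyGrid()
  expect_equal(rmseSpectra(makeSpectrum(g, rep(0.5, 5)),
                           makeSpectrum(g, rep(0.4, 5))), 10)
})

test_that("RMSE is symmetric and scales linearly with a uniform offset", {
  g <- tinyGrid()
  set.seed(14)
  a <- makeSpectrum(g, runif(5, 0.2, 0.7))
  b <- makeSpectrum(g, runif(5, 0.2, 0.7))
  expect_equal(rmseSpectra(a, b), rmseSpectra(b, a))
  for (d in c(0.05, 0.1, 0.2))
    expect_equal(rmseSpectra(a, makeSpectrum(g, spectrumValues(a) + d)),
                 100 * d)
})

test_that("RMSE resampling interpolates the reference onto the measured grid", {
  coarse <- makeGrid(500, 540, 20)  # 3 bands
  fine <- tinyGrid()                # 5 bands at 10 nm
  ref <- makeSpectrum(coarse, c(0.2, 0.4, 0.6))
  measuredVals <- approx(wavelengths(coarse), c(0.2, 0.4, 0.6),
                         xout = wavelengths(fine))$y
  measured <- makeSpectrum(fine, measuredVals)
  expect_error(rmseSpectra(ref, measured), "grids")
  expect_equal(rmseSpectra(ref, measured, resample = TRUE), 0)
})

test_that("DR and SNR agree with 20*log10 closed forms over a ratio grid", {
  expect_equal(dynamicRange(1, 1)$perBandDb, 0)
  expect_equal(dynamicRange(10, 1)$perBandDb, 20)
  expect_equal(dynamicRange(100, 1)$perBandDb, 40)
  expect_equal(snrDb(1000, 10)$perBandDb, 40)
  expect_equal(snrDb(5, 5)$perBandDb, 0)
  # doubling the signal adds 20*log10(2) ~ 6.02 dB
  expect_equal(snrDb(2000, 10)$perBandDb - snrDb(1000, 10)$perBandDb,
               20 * log10(2))
  ratios <- 10^seq(-2, 3, length.out = 40)
  dr <- dynamicRange(ratios, rep(1, 40))
  expect_equal(dr$perBandDb, 20 * log10(ratios))
  expect_equal(dr$globalDb, mean(20 * log10(ratios)))
  sn <- snrDb(ratios, rep(1, 40))
  expect_equal(sn$perBandDb, 20 * log10(ratios))
})

test_that("zero denominators are excluded from globals with a warning", {
  expect_warning(dr <- dynamicRange(c(10, 10), c(1, 0)), "excluded")
  expect_equal(dr$excluded, 2L)
  expect_equal(dr$globalDb, 20)
  expect_warning(sn <- snrDb(c(10, 10), c(1, 0)), "excluded")
  expect_equal(sn$globalDb, 20)
})

test_that("OECF densities, ideal response and residual oracle agree", {
  gray <- seq(0.95, 0.24, length.out = 12)
  dens <- statusTDensity(gray)
  expect_equal(dens[1], 0.02227639, tolerance = 1e-6)
  expect_equal(dens[12], 0.6197888, tolerance = 1e-6)
  # measured == nominal on a perfectly linear system: deviation ~ 0
  oc <- oecf(gray, matrix(rep(gray, each = 4), nrow = 4))
  expect_lt(oc$deviation, 1e-12)
  expect_lt(oc$identityDeviation, 1e-12)
  expect_equal(oc$r2, 1)
  expect_equal(nrow(oc$points), 12)
  # deviation equals a brute-force residual scan over the tiles
  set.seed(8)
  measured <- gray + rnorm(12, 0, 0.02)
  oc <- oecf(gray, measured)
  fit <- lm(measured ~ gray)
  expect_equal(oc$deviation, max(abs(residuals(fit))))
  expect_error(oecf(gray[1:2], measured[1:2]), "3 grayscale")
})

test_that("inter-band RMSE matches arithmetic and flags single-band cubes", {
  g2 <- makeGrid(500, 505, 5)
  arr <- array(0.4, c(6, 6, 2)); arr[, , 2] <- 0.45
  cube <- new("ReflectanceCube", data = arr, grid = g2,
              invalidMask = array(FALSE, dim(arr)))
  ib <- interbandRmse(cube)
  expect_equal(unname(ib$perBandPct), 5)
  expect_equal(ib$meanPct, 5)
  same <- new("ReflectanceCube", data = array(0.4, c(6, 6, 5)),
              grid = tinyGrid(),
              invalidMask = array(FALSE, c(6, 6, 5)))
  expect_true(all(interbandRmse(same)$perBandPct == 0))
  one <- new("ReflectanceCube", data = array(0.4, c(6, 6, 1)),
             grid = makeGrid(500, 505, 5, "half_open"),
             invalidMask = array(FALSE, c(6, 6, 1)))
  expect_error(interbandRmse(one), "2 bands")
})

test_that("characterization reports assemble and compare consistently", {
  set.seed(41)
  sys <- systemPreset("clinical_dual_lctf")
  g <- sys@grid
  scene <- makeRezCheckerScene(g, patchPx = 8, gapPx = 2)
  p <- constantProfile(g, 80)
  raw <- simulateCube(scene, sys, p)
  white <- simulateCube(makeFlatScene(g, 1, scene@nrow, scene@ncol), sys, p)
  dark <- simulateCube(makeFlatScene(g, 0, scene@nrow, scene@ncol), sys, p)
  rep1 <- characterizeSystem(raw, white, dark, scene, sys)
  expect_equal(rep1@meta$bands, 109)
  expect_equal(rep1@meta$rangeNm, c(460, 1000))
  expect_equal(rep1@meta$fwhmNm, 18)
  # global aggregation is the unweighted band mean
  expect_equal(rep1@drGlobalDb, mean(rep1@drDb, na.rm = TRUE))
  expect_equal(rep1@snrGlobalDb, mean(rep1@snrDb, na.rm = TRUE))
  # the reported maximum-SNR band is the argmax of the series
  expect_equal(rep1@meta$maxSnrBandNm,
               wavelengths(g)[which.max(rep1@snrDb)])
  # comparing a report with itself gives identical columns
  tab <- compareSystems(list(rep1, rep1))
  expect_identical(tab[[2]], tab[[3]])
  expect_equal(tab[tab$metric == "Number of bands", 2], "109")
  expect_error(compareSystems(list(rep1)), "two reports")
})

test_that("variable exposure flattens per-band SNR across the spectrum", {
  set.seed(55)
  sys <- systemPreset("clinical_dual_lctf")
  sys@transitionMagnitude <- 1
  g <- sys@grid
  wl <- wavelengths(g)
  sweep <- simulateWhiteCaptures(sys, wl, 120, nPix = 4096)
  eff <- characterizeEfficiency(sweep, darkLevel = 40 + 0.01 * 120)
  prof <- solveExposure(eff, 3000, 300, grid = g)
  scene <- makeFlatScene(g, 0.95, 16, 16)
  snrOf <- function(p) {
    cube <- simulateCube(scene, sys, p)
    s <- extractRoiSpectrum(cube, makeRoi(8, 8, 16))
    db <- snrDb(spectrumValues(s$mean), spectrumValues(s$sd))$perBandDb
    db
  }
  snrVar <- snrOf(prof)
  snrConst <- snrOf(constantProfile(g, 100))
  expect_lt(var(snrVar), var(snrConst))
})
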