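# Efficiency characterization, the exposure solver, spline densification
# and acquisition-time budgeting.

test_that("efficiency is signal above dark per millisecond", {
  eff <- characterizeEfficiency(
    data.frame(wavelengthNm = 650, meanDn = 2550, exposureMs = 250),
    darkLevel = 50)
  expect_equal(eff@dnPerMs, 10)
  expect_warning(
    e0 <- characterizeEfficiency(
      data.frame(wavelengthNm = 650, meanDn = 50, exposureMs = 250),
      darkLevel = 50),
    "dark level")
  expect_equal(e0@dnPerMs, 0)
  expect_error(characterizeEfficiency(data.frame(), 0), "non-empty")
  # a 20 nm characterization sweep over 650-1090 nm has 23 knots
  sweep <- data.frame(wavelengthNm = seq(650, 1090, by = 20),
                      meanDn = 1000, exposureMs = 100)
  expect_length(characterizeEfficiency(sweep, 50)@wavelengthsNm, 23)
})

test_that("the solver hits target/efficiency and caps low-sensitivity bands", {
  knots <- data.frame(wavelengthNm = c(650, 670, 690, 710),
                      meanDn = c(2050, 1050, 550, 50), exposureMs = 100)
  expect_warning(eff <- characterizeEfficiency(knots, darkLevel = 50),
                 "dark level")  # 20, 10, 5, 0 DN/ms
  p <- solveExposure(eff, 3000, 300)
  expect_equal(exposureTimes(p), c(150, 300, 300, 300))
  # an uncapped solution of exactly 300 ms sits at the cap without a flag
  expect_equal(lowSensitivityBands(p), c(FALSE, FALSE, TRUE, TRUE))
  # eff 10 DN/ms with target 3000 and cap 300 is exactly at the flag edge
  p2 <- solveExposure(characterizeEfficiency(
    data.frame(wavelengthNm = c(650, 670), meanDn = 1050, exposureMs = 100),
    50), 3000, 300)
  expect_equal(exposureTimes(p2), c(300, 300))
  expect_false(any(lowSensitivityBands(p2)))
  # halving efficiency doubles the uncapped exposure
  pa <- solveExposure(characterizeEfficiency(
    data.frame(wavelengthNm = c(650, 670), meanDn = 2050, exposureMs = 100),
    50), 1000, 1e5)
  pb <- solveExposure(characterizeEfficiency(
    data.frame(wavelengthNm = c(650, 670), meanDn = 1050, exposureMs = 100),
    50), 1000, 1e5)
  expect_equal(exposureTimes(pb), 2 * exposureTimes(pa))
  # unreachable target
  expect_error(solveExposure(eff, 5000, 300, saturationDn = 4095),
               "saturation")
})

test_that("densification is shape preserving and re-applies the cap", {
  knotGrid <- makeGrid(650, 690, 20)
  dense <- makeGrid(650, 690, 5)
  mkProfile <- function(t, cap = 300) new("ExposureProfile",
    grid = knotGrid, tMs = pmin(t, cap), tUncappedMs = t, targetDn = 3000,
    tMaxMs = cap, strategy = "custom", lowSensitivity = t > cap)
  # constant knots stay constant
  d <- densifyProfile(mkProfile(rep(250, 3)), dense)
  expect_equal(exposureTimes(d), rep(250, 9))
  # knots are interpolated exactly
  p <- mkProfile(c(100, 300, 280))
  d <- densifyProfile(p, dense)
  at <- match(wavelengths(knotGrid), wavelengths(dense))
  expect_equal(exposureTimes(d)[at], c(100, 300, 280))
  # no overshoot above the largest knot, unlike a natural cubic spline
  expect_lte(max(exposureTimes(d)), 300)
  natural <- stats::spline(wavelengths(knotGrid), c(100, 300, 280),
                           xout = wavelengths(dense), method = "natural")$y
  expect_gt(max(natural), 300)  # the oracle overshoots the cap
  # bounded by the knot range
  set.seed(4)
  for (i in 1:10) {
    t <- runif(3, 50, 290)
    d <- densifyProfile(mkProfile(t), dense)
    expect_gte(min(exposureTimes(d)), min(t) - 1e-9)
    expect_lte(max(exposureTimes(d)), max(t) + 1e-9)
  }
  expect_error(densifyProfile(mkProfile(rep(1, 3)),
                              makeGrid(650, 655, 5)), NA)
})

test_that("densifying the uncapped solution re-flags capped bands", {
  knotGrid <- makeGrid(650, 690, 20)
  dense <- makeGrid(650, 690, 5)
  p <- new("ExposureProfile", grid = knotGrid, tMs = c(200, 300, 300),
           tUncappedMs = c(200, 500, 900), targetDn = 3000, tMaxMs = 300,
           strategy = "custom", lowSensitivity = c(FALSE, TRUE, TRUE))
  d <- densifyProfile(p, dense)
  expect_true(all(exposureTimes(d) <= 300))
  # flags appear where the interpolated uncapped curve crosses the cap
  expect_true(any(lowSensitivityBands(d)))
  expect_false(lowSensitivityBands(d)[1])
  expect_true(all(lowSensitivityBands(d)[wavelengths(dense) >= 670]))
})

test_that("total acquisition time sums exposures plus per-band overhead", {
  g <- makeGrid(650, 1100, 5, "half_open")
  p <- constantProfile(g, 250)
  expect_equal(totalAcquisitionTime(p), 22.5)
  expect_equal(totalAcquisitionTime(numeric(0)), 0)
  o <- 7
  expect_equal(totalAcquisitionTime(p, overheadMs = o),
               22.5 + 90 * o / 1000)
})

test_that("exposure profiles round trip through the two-column text format", {
  knots <- data.frame(wavelengthNm = seq(650, 710, 20),
                      meanDn = c(2050, 1050, 550, 150), exposureMs = 100)
  p <- solveExposure(characterizeEfficiency(knots, 50), 3000, 300)
  path <- file.path(withr::local_tempdir(), "profile.tsv")
  writeExposureProfile(p, path)
  back <- readExposureProfile(path)
  expect_equal(exposureTimes(back), exposureTimes(p))
  expect_equal(lowSensitivityBands(back), lowSensitivityBands(p))
  expect_equal(back@targetDn, 3000)
  expect_equal(back@tMaxMs, 300)
  expect_equal(wavelengths(back), wavelengths(p))
  # constant profiles (NA target) survive too
  cp <- constantProfile(tinyGrid(), 250)
  writeExposureProfile(cp, path)
  expect_equal(exposureTimes(readExposureProfile(path)), rep(250, 5))
})

test_that("the noiseless trade-off limit recovers the reference almost exactly", {
  efs <- systemPreset("nir_lab_efs")
  zen <- makeZenithLikeReference(efs@grid, seed = 2)
  curve <- exposureTradeoffCurve(efs, zen$spectrum, framePx = 8,
                                 noise = FALSE)
  # only quantization of the DN remains
  expect_true(all(curve$rmsePct < 0.2))
  expect_equal(curve$strategy, c("constant", "short_limit", "long_limit"))
})

test_that("trade-off summary reproduces hand arithmetic", {
  s <- tradeoffSummary(data.frame(
    strategy = c("constant", "short_limit", "long_limit"),
    totalTimeS = c(28, 32, 50), rmsePct = c(26, 12, 5)))
  expect_equal(s$reductionPct, c(0, 100 * 14 / 26, 100 * 21 / 26))
  expect_equal(s$reductionPctPerS[2], 100 * 14 / 26 / 4)
  expect_true(is.na(s$reductionPctPerS[1]))
})
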