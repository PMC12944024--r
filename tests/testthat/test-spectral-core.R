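# Wavelength grids, ROI statistics and their invariants.

test_that("grid band counts follow the closed/half-open formulas", {
  expect_equal(nBands(makeGrid(460, 1000, 5, "closed")), 109)
  expect_equal(nBands(makeGrid(650, 1100, 5, "half_open")), 90)
  expect_equal(wavelengths(makeGrid(500, 505, 5, "closed")), c(500, 505))

  set.seed(31)
  for (i in 1:25) {
    step <- sample(c(1, 2, 5, 10, 20), 1)
    n <- sample(2:60, 1)
    start <- sample(400:900, 1)
    end <- start + n * step
    expect_equal(nBands(makeGrid(start, end, step, "closed")), n + 1)
    expect_equal(nBands(makeGrid(start, end, step, "half_open")), n)
    wl <- wavelengths(makeGrid(start, end, step, "closed"))
    expect_true(all(diff(wl) == step))
  }
})

test_that("invalid grid requests raise informative errors", {
  expect_error(makeGrid(460, 1003, 5), "remainder")
  expect_error(makeGrid(460, 1000, 0), "stepNm")
  expect_error(makeGrid(460, 1000, -5), "stepNm")
  expect_error(makeGrid(1000, 460, 5), "startNm")
})

test_that("ROI statistics match brute-force oracles (population SD)", {
  # uniform cube: mean equals the fill, SD zero
  s <- extractRoiSpectrum(tinyCube(fill = 100L), makeRoi(2, 2, 2))
  expect_equal(spectrumValues(s$mean), rep(100, 5))
  expect_equal(spectrumValues(s$sd), rep(0, 5))

  # 2x2 block holding 1,2,3,4 in every band
  g <- tinyGrid()
  arr <- array(0L, c(4, 4, 5))
  for (b in 1:5) arr[1:2, 1:2, b] <- matrix(c(1L, 2L, 3L, 4L), 2)
  cube <- hscolpo:::.newHSCube(arr, g, 10, rep(1, 5))
  s <- extractRoiSpectrum(cube, makeRoi(1, 1, 2))
  expect_equal(spectrumValues(s$mean), rep(2.5, 5))
  expect_equal(spectrumValues(s$sd), rep(sqrt(mean((1:4 - 2.5)^2)), 5))

  # random cubes against an explicit pixel-listing oracle
  set.seed(7)
  for (i in 1:10) {
    arr <- array(sample.int(1023L, 8 * 8 * 5, replace = TRUE), c(8, 8, 5))
    cube <- hscolpo:::.newHSCube(arr, g, 10, rep(1, 5))
    k <- sample(1:5, 1)
    roi <- makeRoi(sample(3:6, 1), sample(3:6, 1), k)
    s <- extractRoiSpectrum(cube, roi)
    rows <- hscolpo:::.roiRows(roi); cols <- hscolpo:::.roiCols(roi)
    for (b in c(1, 5)) {
      px <- as.vector(arr[rows, cols, b])
      expect_equal(spectrumValues(s$mean)[b], mean(px))
      expect_equal(spectrumValues(s$sd)[b],
                   sqrt(sum((px - mean(px))^2) / length(px)))
    }
  }
})

test_that("a 10x10 ROI covers exactly 100 pixels and counts saturation", {
  g <- tinyGrid()
  arr <- array(500L, c(12, 12, 5))
  arr[3, 3, 2] <- 1023L  # one saturated voxel at the 10-bit top code
  cube <- hscolpo:::.newHSCube(arr, g, 10, rep(1, 5))
  roi <- makeRoi(6, 6, 10)
  expect_length(hscolpo:::.roiRows(roi), 10)
  s <- extractRoiSpectrum(cube, roi)
  expect_equal(s$nSaturated, c(0L, 1L, 0L, 0L, 0L))
  expect_equal(spectrumValues(s$mean)[2], (99 * 500 + 1023) / 100)
})

test_that("out-of-bounds ROIs are rejected", {
  cube <- tinyCube(nrow = 4, ncol = 4)
  expect_error(extractRoiSpectrum(cube, makeRoi(1, 1, 4)), "outside")
  expect_error(extractRoiSpectrum(cube, makeRoi(4, 4, 3)), "outside")
})

test_that("saturation mask is enforced by the container", {
  g <- tinyGrid()
  arr <- array(100L, c(2, 2, 5))
  expect_error(new("HSCube", data = arr, grid = g, bitDepth = 10L,
                   exposureMs = rep(1, 5),
                   saturated = array(TRUE, dim(arr)),
                   artefactBands = integer()),
               "saturated")
  expect_error(hscolpo:::.newHSCube(array(5000L, c(2, 2, 5)), g, 10, rep(1, 5)),
               "DN values")
})

test_that("constant spectra and reflectance overshoot are flagged correctly", {
  g <- tinyGrid()
  s <- makeSpectrum(g, c(0.2, 0.5, 1.01, 0.9, 1.0))
  expect_equal(which(reflectanceOvershoot(s)), 3L)
  expect_error(makeSpectrum(g, rep(3, 5)), "reflectance")
})
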