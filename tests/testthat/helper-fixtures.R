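# Shared fixtures built in code. Small grids and systems keep the suite
# fast; the system helpers wrap the presets so individual tests can tweak
# noise terms without repeating the construction.

tinyGrid <- function() makeGrid(500, 540, 10)  # 5 bands

# deterministic DN cube with known values
tinyCube <- function(nrow = 4, ncol = 4, grid = tinyGrid(), bitDepth = 10,
                     fill = 100L) {
  nb <- nBands(grid)
  hscolpo:::.newHSCube(array(as.integer(fill), c(nrow, ncol, nb)),
                       grid, bitDepth, rep(10, nb))
}

# minimal ideal system: flat illuminant, rectangular unit passband, flat
# QE, no dark, no read noise -- closed forms are exact on it
idealSystem <- function(grid = tinyGrid(), qe = 0.5, width = 10,
                        gain = 0.1, bitDepth = 12, throughput = 1,
                        darkOffsetDn = 0, darkRateDnPerMs = 0,
                        readNoiseRms = 0) {
  makeOpticalSystem(
    name = "ideal",
    illuminant = makeIlluminant("custom", fun = function(l) rep(1, length(l))),
    passband = makePassband(range(wavelengths(grid)) + c(-50, 50),
                            fwhmNm = width, peakTransmission = 1,
                            leakage = 0, shape = "rect"),
    sensor = makeSensor(function(l) rep(qe, length(l)), bitDepth = bitDepth,
                        gain = gain, readNoiseRms = readNoiseRms,
                        darkRateDnPerMs = darkRateDnPerMs,
                        darkOffsetDn = darkOffsetDn),
    grid = grid, throughput = throughput)
}

expectProfile <- function(grid, tMs) constantProfile(grid, tMs)
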