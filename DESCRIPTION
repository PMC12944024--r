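Package: hscolpo
Title: Simulation and Radiometric Characterization of LCTF-Based
    Hyperspectral Colposcopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and quality-control toolkit for narrow-band
    illumination hyperspectral imaging systems built around liquid-crystal
    tunable filters (LCTFs), as used in hyperspectral colposcopy. Models the
    full acquisition chain (broadband illuminant, tunable Gaussian passband,
    wavelength-dependent sensor quantum efficiency, shot/read/dark noise and
    10- or 12-bit quantization), implements adaptive wavelength-dependent
    exposure control towards a target digital number with a per-band cap,
    white/dark reflectance calibration, and a characterization suite:
    spectral RMSE against a reference standard, per-band dynamic range and
    signal-to-noise ratio in dB, OECF radiometric-linearity analysis on a
    stepped grayscale target, and inter-band RMSE for motion-artefact
    detection in spatio-spectral scanning. Includes band-sequential ENVI-style
    cube I/O and reproducible, seeded laboratory experiment presets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    pracma
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectral-core.R'
    'cube-io.R'
    'forward-sim.R'
    'scenes.R'
    'presets.R'
    'exposure-control.R'
    'calibration.R'
    'characterization.R'
    'pipeline.R'
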