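---
title: "Methods: simulating and characterizing LCTF-based hyperspectral acquisition"
author: "hscolpo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterizing LCTF-based hyperspectral acquisition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hscolpo)
```

This vignette is the package's account of its science: the forward model
and its assumptions, the exposure-control method, the QC metrics, the
choices made where the design was genuinely open, and what the synthetic
experiments do and do not demonstrate about real hardware.

## The forward model

A narrow-band-illumination hyperspectral system acquires one full frame
per tuned filter position. We model the expected digital number of a
pixel with reflectance $R$ at band center $c$ and exposure $t$ (ms) as

$$\mathrm{DN}(c,t,R) = \mathrm{clip}\!\left(d_0 + d_r t + g\,\tau\, t\, R
\int E(\lambda)\, T(\lambda; c)\, QE(\lambda)\, d\lambda,\; 0,\; 2^b-1\right)$$

* $E(\lambda)$ — relative illuminant power. Presets: a 3200 K thermal
  (halogen-like) emitter supported on 400–1750 nm; a flat high-CRI LED on
  420–700 nm with soft sigmoid edges; and their combination for the
  dual-filter clinical preset.
* $T(\lambda;c)$ — Gaussian passband with wavelength-dependent FWHM.
  LCTF bandwidth grows with wavelength; we use a linear FWHM ramp across
  the tuning range (9→24 nm for the laboratory filter; 12→24 nm for the
  clinical preset so that the average over its grid is 18 nm). A
  rectangular shape exists for closed-form validation. Out-of-band
  leakage is a small constant floor (default $10^{-4}$) integrated over
  the full illuminant support.
* $QE(\lambda)$ — sensor quantum efficiency, a shape-preserving (PCHIP)
  curve through anchor points. The NIR laboratory sensor peaks at 0.60
  near 600 nm and falls to 0.05 at 1000 nm; the clinical 12-bit sensor
  holds 0.72 over 525–580 nm.
* $g$ — gain in DN per photoelectron, so the shot-noise variance of a
  signal $s$ DN is $g\,s$ DN². $d_0$, $d_r$ — dark offset and dark rate;
  read noise is additive Gaussian; values are rounded and clipped to the
  $b$-bit code range, and the saturation mask marks voxels at the top
  code exactly.

**Photon units are abstracted.** Only relative radiometry is modeled:
each preset scales its illuminant so that the most sensitive band of its
grid reaches a stated peak signal rate (30 DN/ms for the clinical preset,
3.2 for the laboratory one, at unit reflectance). This pins the DN scale
the way source power and aperture would; absolute radiance is out of
scope.

**Noise draw order** is fixed and documented (transition jitter, then
per band: shot noise for all pixels, then read noise), so one integer
seed reproduces any cube bit-exactly.

### Filtering geometries

The emission-filtering preset (`nir_lab_efs`) and the reception-filtering
preset (`nir_lab_rfs`) share source, optics and sensor; the reception
geometry inserts a long-working-distance beamsplitter and loses 87.5% of
the light ($\tau = 0.125$). Because the model is affine in $t$, matching
a given DN therefore needs exactly $8\times$ the exposure — the package
reproduces the 250 ms ↔ 2000 ms pairing as a pure consequence of the
throughput deficit.

### Dual-filter transition artefact

The clinical preset hands over between two filters at 720–740 nm; the
hand-over (a motorized mirror realigning two optical paths) perturbs the
affected bands. We model it as a band-local multiplicative factor
(default 1.15) whose per-acquisition effective magnitude carries seeded
jitter (SD 30% of the excess). The jitter matters: a perfectly
repeatable gain error would cancel exactly in white-reference
calibration, whereas the real artefact survives calibration as a bump in
the 720–740 nm region. The standalone `injectFilterTransition()`
operation, by contrast, is exact and deterministic, and flags the bands
it touched. Affected bands are always recorded in cube metadata.

### Spatio-spectral scanning and motion

`simulateSpatioScanCube()` emulates a sensor whose spectral filters are
aligned with columns: band $b$ at column $c$ is assembled from frame
$b + c - 1$ (nearest-frame assignment), and the scene shifts between
frames according to a `MotionModel`. Zero amplitude reproduces the
spectral-scanning output exactly (identical noiseless cubes). The
default schedule is a deterministic sinusoid (three periods per scan,
emulating respiration); a seeded random walk and a constant drift are
also available. Column-dependent displacement that differs between
consecutive bands produces the characteristic vertical banding, which
the inter-band RMSE quantifies.

## Exposure control

The method has four stages, each a package operation:

1. **Characterization** — white-reference captures every 20 nm at one
   reference exposure; efficiency is signal above dark per ms,
   $\mathrm{eff}(\lambda) = (\overline{\mathrm{DN}} - \mathrm{dark})/t$.
   Samples at or below the dark level are clamped to zero efficiency
   with a warning.
2. **Solution** — $t(\lambda) = \min(\mathrm{target}/\mathrm{eff}(\lambda),
   t_{\max})$. The target is interpreted as signal *above dark*, which
   makes the solution invariant to the dark level (the alternative —
   target as absolute DN — would couple the solved exposures to $d_0$
   for no physical reason). Bands whose uncapped solution exceeds the
   cap are flagged low-sensitivity; a target at or above the top code is
   rejected as unreachable without saturation.
3. **Densification** — the *uncapped* solution is interpolated from the
   20 nm knots onto the 5 nm acquisition grid with a monotone cubic
   Hermite (PCHIP) spline and the cap is re-applied. PCHIP passes
   through the knots exactly and cannot overshoot beyond neighboring
   knot values; a natural cubic spline can, which would silently break
   the cap between knots (the test suite demonstrates the overshoot on
   the knot triple 100/300/280 ms). Beyond the outermost knots the
   nearest knot value is held — extrapolating a polynomial into an
   uncharacterized region has no support in the data.
4. **Budgeting** — total time is $\sum t + N\cdot\mathrm{overhead}$, in
   seconds. Per-band overhead defaults to 0 and is configurable;
   real systems add filter-tuning and readout overheads that we do not
   model, so simulated totals are not comparable to wall-clock times of
   physical devices.

Three named strategies are built in: `constant` (250 ms everywhere),
`short_limit` (cap 500 ms) and `long_limit` (cap 1200 ms); the clinical
profile uses the short-limit strategy with a 300 ms cap and a 3000 DN
target for the 12-bit sensor.

### The trade-off experiment

`exposureTradeoffCurve()` runs the full chain per strategy
(characterize → solve → densify → simulate white/dark/target →
calibrate → spectral RMSE against ground truth) and pairs each RMSE with
the total acquisition time. Two design points:

* The reported RMSE is the root mean of squared RMSEs over
  `nRepeats = 6` independent acquisitions. A single acquisition's RMSE
  carries large sampling noise — each band contributes one realized
  noise draw, so the estimate has only as many effective degrees of
  freedom as there are noise-dominated bands — and orderings between
  similar strategies can tie by chance. Averaging repeats is the
  standard repeated-measurement remedy and makes the estimator
  consistent.
* In the noiseless limit the chain recovers the reference almost
  exactly (only DN rounding remains), which separates the stochastic
  behavior of the strategies from any systematic error in the chain.

On the declining-efficiency laboratory preset the expected ordering —
RMSE(long) < RMSE(short) < RMSE(constant) with the opposite ordering of
acquisition times, and a larger RMSE-reduction-per-extra-second for the
short cap than the long one — emerges from the physics: the constant
exposure underexposes the NIR bands, the short cap rescues them up to
~970 nm, and the long cap extends sensitivity further at a
disproportionate time cost.

## Calibration and QC metrics

* **Flat-field calibration**: $R = (\mathrm{raw} - \mathrm{dark}) /
  (\mathrm{white} - \mathrm{dark})$ per voxel and band; references may
  be full cubes or per-band mean spectra (both appear in practice, and
  which one a given protocol uses is rarely stated). Voxels with
  $\mathrm{white}-\mathrm{dark} \le 1$ DN or saturated raw/white data
  are masked invalid rather than clipped; values slightly above 1 from
  noise are retained so that downstream error statistics stay unbiased.
* **Spectral RMSE** is computed on reflectance fractions and reported
  ×100 (percent). When grids differ, the *reference* is linearly
  interpolated onto the measurement grid — the measurement is the noisy
  quantity and should not be resampled.
* **DR and SNR**: $20\log_{10}$ of the bright/dark mean ratio and of the
  mean/SD ratio, per band; global values are unweighted band means;
  zero denominators exclude a band from the global with a warning.
  Following the chart-based protocol, both levels come from grayscale
  tiles: the brightest (95%) tile supplies the signal and the *darkest
  available* tile (24% nominal) stands in for the nominal "20%
  reflectance element" — the chart simply has no 20% tile, and the
  substitution is recorded in the report's warnings. This bounds the
  chart-based DR near $20\log_{10}(0.95/0.24) \approx 12$ dB; a
  true dark frame would give the much larger sensor-level DR, and the
  reported quantity should be read as chart contrast ratio, not full
  sensor dynamic range.
* **OECF**: points are (status T density $-\log_{10}\rho$, measured
  reflectance). The linearity deviation is the maximum absolute
  residual from the least-squares line of measured against *nominal
  reflectance*. We deliberately do not fit the line in density space:
  reflectance versus density is $10^{-D}$, i.e. curved, so even an
  ideal system would show a spurious "deviation" there (~0.075 on this
  chart); in reflectance-vs-reflectance space the ideal response is the
  identity and the deviation is exactly zero for any radiometrically
  linear (indeed any affine) system. The departure from the ideal
  response itself is reported separately as `identityDeviation`.
* **Inter-band RMSE**: per band $i \ge 2$, the RMSE over all valid
  pixels between bands $i$ and $i-1$ (percent), computed on calibrated
  reflectance by default — raw DN would confound scene change with
  illumination/sensitivity change between bands.

## The synthetic targets

* `makeRezCheckerScene()` builds a 6 × 7 matrix of color patches with
  flat or gently sloped deterministic spectra plus a 12-tile grayscale
  stepping from 0.95 to 0.24 nominal reflectance. It is a synthetic
  stand-in with the published *structure* of a calibrated chart; the
  true per-patch spectra of any physical chart are proprietary and are
  not emulated.
* `makeZenithLikeReference()` builds a smooth baseline near 0.9 with
  3–5 narrow Gaussian absorption dips at seeded positions and returns
  the dip parameters as ground truth. It stands in for a rare-earth
  diffuse reflectance standard whose manufacturer spectrum is not
  public. Consequently, absolute RMSE values measured against real
  standards by physical systems are **not** reproducible here — only
  orderings and recovery properties are meaningful, and only those are
  asserted.

## Statistical design of the checks

Parameter-recovery checks compare a measured mean against its target
within 3 standard errors, where the SE is that of the measured mean
under the full noise model (shot + read + quantization, plus the
characterization uncertainty propagated through the solver). Two notes:

* A "within 3 SE for every band" check across ~100 bands is a
  familywise statement: even a perfect implementation fails it with
  probability ≈ 0.2 for an arbitrary seed. The test suite runs it at a
  fixed seed; the acceptance script reports the max-|z| statistic
  rather than asserting it.
* The solver-recovery check runs with the transition artefact disabled:
  the artefact is a gain perturbation orthogonal to the exposure
  method, and leaving it on would turn a check of the solver into a
  check of the artefact model on the five affected bands.

## Problem sizes

Simulated frames in the experiments are 16–98 pixels per side and cubes
have 28–109 bands; ROI statistics use 10 × 10 tiles (5 × 5 for in-vivo
style spectra). These sizes give the checks comfortable statistical
power — e.g. a 16 × 16 ROI mean at 3000 DN has a shot SE of ~1.5 DN —
while keeping every experiment in the seconds range; they are stated
here as the package's chosen study conditions.

## Known limitations

* No physical optics: diffraction, polarization inside the LCTF, stray
  light, chromatic aberration and spatial illumination nonuniformity are
  not modeled; calibration is purely the reference division.
* The spatio-spectral reconstruction uses nearest-frame assignment, the
  simplest model that yields the vertical banding artefact; real
  Snapscan reconstruction interpolates between frames.
* Sensor QE curves, the dual-source illuminant and the transition
  artefact form are smooth synthetic stand-ins anchored at published
  summary values (peak QE, plateau ranges, dark levels), not measured
  device curves.
* Grid conventions differ between published descriptions of the same
  instrument family (90 bands over 650–1100 nm is a half-open count;
  109 over 460–1000 nm is closed). Both conventions are first-class
  here and every preset documents which one it uses; no single
  convention reproduces every published band count, including a "130
  bands" figure that matches neither range at 5 nm.
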