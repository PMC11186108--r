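---
title: "Methods: simulating an end-to-end validation of image-based RPT dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating an end-to-end validation of image-based RPT dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package simulates

Voxel-level dosimetry for radiopharmaceutical therapy (RPT) turns a
quantitative SPECT/CT image into a 3-D absorbed-dose map: the SPECT volume
defines where the radionuclide is, the CT defines the materials it decays
in, and a Monte Carlo engine transports the emitted radiation. Validating
such a workflow end to end requires an independent dose measurement, and
thermoluminescent dosimeters (TLDs) mounted inside a phantom are the
standard instrument for that.

`rptdose` reproduces the whole validation loop in software, at desk scale:
a 6.4 L water cylinder holds a 16 ml sphere filled with 748 MBq of I-131
and six acrylic probes, each carrying a stack of four TLD chips. The
pipeline generates a synthetic SPECT counts volume and a CT-like density
volume from this phantom, quantifies the SPECT image back to absolute
activity, computes absorbed dose by Monte Carlo in two modes — from the
quantified image ("image mode") and from the analytic source geometry
("idealized mode") — reduces synthetic TLD readings to measured doses, and
reports per-probe agreement against an uncertainty budget.

Because every stage consumes only the outputs of the previous one, closure
of the loop (measured dose agreeing with image-based dose) exercises the
same error chain a physical validation does: partial-volume losses,
calibration, resampling, transport physics, and measurement reduction.

## Decay bookkeeping

Activity follows `A(t) = A_admin e^{-λt}` with `λ = ln 2 / T_1/2` and
`T_1/2 = 8.0197 d` for I-131. The cumulated activity over an exposure
window `t_e`,

```
Ã = (A_admin / λ) (1 − e^{−λ t_e}),   [Bq·s]
```

converts a per-history Monte Carlo dose (one history = one decay) to gray:
`D = Ã × D_history`. With the study parameters (748 MBq, 16.87 d) this
gives `Ã = 5.737e14 Bq·s`. Times are days at every interface and are
converted to seconds exactly once, inside `integrated_activity()`.

In image mode the pipeline does not know `A_admin`; it integrates the
*imaged* activity, decay-corrected from scan time (7.1 d) back to
administration, over the same exposure window. The residual difference
between the two cumulated activities is exactly the quantification error,
which is the quantity the validation is designed to surface.

Emission data (five principal gamma lines plus xenon K x-rays, and a mean
electron energy of 191.9 keV per decay covering the beta spectrum plus
conversion and Auger electrons) ship as a CSV compiled from published
decay-data evaluations and can be overridden.

## The image-formation surrogate

The scanner model replaces projection-domain physics (OSEM reconstruction,
collimator-detector response, triple-energy-window scatter correction)
with an image-domain surrogate: conservative resampling of the true
activity onto the 128³ × 4.42 mm SPECT grid, an isotropic Gaussian PSF,
a global sensitivity × duration scale, and post-blur Poisson noise. The
surrogate reproduces the phenomena the downstream corrections exist for
(partial-volume spill-out, count statistics, counts-to-activity
calibration) but not reconstruction artifacts: Gibbs ringing, which real
I-131 images show near sharp sources, is absent, and noise is exactly
Poisson rather than spatially correlated. Passing closure tests therefore
demonstrates the correctness of the quantification and dose chain, not the
fidelity of any particular scanner.

Defaults: PSF FWHM 12 mm (representative of high-energy general-purpose
collimation at 364 keV; the true value is scanner-specific and is a free
parameter), sensitivity 1.4e-5 counts/s/Bq over a 3600 s acquisition
(120 × 30 s), which yields ≈2e7 total counts — a realistic count level at
7.1 days post administration, chosen to make Poisson noise visible but not
dominant. Absolute counts never enter any validation target; only ratios
do.

## Quantification

The calibration factor (Bq per count) is total truth activity over total
counts of a uniformly filled 5.64 L cylinder scan — unbiased for a uniform
source imaged by a count-conserving system. Background is then zeroed
outside the source-sphere VOI, and the volume-averaged recovery
coefficient (RC) for the 16 ml sphere, measured on the same scanner model
from a noise-free sphere scan quantified with the same calibration factor,
rescales the in-VOI activity. RC is applied as a uniform in-VOI factor;
voxel-level partial-volume correction is not attempted, since a
volume-averaged coefficient carries no voxel-scale information.

Two deliberate simplifications are documented rather than hidden:

* the VOI is the *analytic* sphere rasterized on the working grid, not an
  image segmentation — this isolates quantification arithmetic from
  segmentation error;
* the quantification support is every voxel within
  `radius + half a voxel diagonal` of the sphere center, and the apparent
  mean concentration is total in-support activity over the analytic
  volume. This estimator is exact for a blur-free source (so RC → 1 as
  PSF → 0 holds to machine precision), and because the identical
  estimator is used when measuring RC and when quantifying, any
  support-definition bias cancels in the corrected result.

Activity is resampled to the dose grid (247 × 253 × 52 at
0.977 × 0.977 × 5.0 mm) by trilinear interpolation of *concentration*
(the intensive quantity), with per-voxel Bq recomputed on the target voxel
volume; interpolating extensive per-voxel activity directly would imprint
the spacing ratio on the result. The relative change of the VOI mean
across resampling is reported as a diagnostic.

Percent differences throughout use `100 · (A − reference) / reference`,
and the decay-corrected administered concentration at scan time is the
reference for quantification residuals.

## Monte Carlo dose engine

Analog photon transport runs over the voxel material grid with Woodcock
(delta) tracking: free paths are sampled from an energy-dependent majorant
attenuation coefficient (the per-energy maximum across materials), and
fictitious collisions keep the tracking exact in heterogeneous media
without voxel-boundary ray tracing. At a real collision the interaction is
photoelectric (full local deposit) or incoherent scattering with exact
Klein–Nishina free-electron sampling (composition-rejection); the electron
energy deposits in the collision voxel and the photon continues. Photons
terminate below 10 keV (local deposit) or on grid exit (tallied as
escaped). Per batch, deposited + escaped energy equals emitted energy
exactly — an identity the test suite asserts rather than assumes.

Electrons are not transported: the mean per-decay electron energy deposits
in the emission voxel. The I-131 beta spectrum's CSDA range in water is
about 2 mm at the (rare) endpoint and far less at the mean — below the
dose-grid spacing in two axes — so this is the standard local-deposition
approximation, and probe doses (outside the source) are photon-dominated,
which is precisely the component the TLD measurement scores. Coherent
scattering, characteristic x-rays and bremsstrahlung are omitted:
few-percent effects in low-Z media at 80–723 keV, small against the 10%
acceptance envelope.

Interaction coefficients ship as a CSV computed by the package itself:
exact Klein–Nishina incoherent cross sections times electron density, plus
a photoelectric power law anchored at the water photoelectric/Compton
crossover (≈26 keV) and scaled across materials by effective atomic
number. The table reproduces water's total attenuation near 364 keV to
about 1% (coherent scattering excluded by design). It is data, not code:
point the loader at a different CSV to use measured compilations.

Cubic 5 mm scorers at the TLD positions accumulate track-length fluence
spectra (5 keV bins, 0–730 keV); their fluence-weighted mean energies feed
the TLD energy correction. In the default geometry they fall at
237–296 keV — below the 364.5 keV photopeak, as scatter downshift
requires, and within the range such probes see in water at these depths.

Probe doses themselves use a track-length (kerma-style) estimator in the
same scorers: every photon segment crossing a scorer contributes its
expected collision deposit, `μ(E)·ℓ·[f_pe·E + (1−f_pe)·E(1−⟨ε⟩_KN)]`, with
the mean Klein–Nishina scattered fraction computed from the same tables
the transport samples from. Under the local-electron-deposition model this
estimator is consistent in expectation with the collision estimator but
has far lower variance in a 0.125 ml volume, because every crossing photon
contributes rather than the rare colliding one. The per-voxel dose grid
remains collision-based (analog energy deposition), and the generic
`roi_mean_dose()` over the dose grid is available for arbitrary regions.

Statistical uncertainty comes from 10 independent batches (batch index
folded into the seed stream): scorer-dose uncertainties are the standard
error of the batch means — an honest estimate that includes all
within-batch correlation — while per-voxel uncertainties use batch
variances voxel-wise. A caution documented from our own convergence
study: propagating per-voxel variances into a small ROI "assuming
independence" understates the true ROI uncertainty severalfold, because
one photon deposits in several neighboring voxels; the batch-level scorer
statistic is the reliable number. Default histories — 2e7 decays in image
mode, 4e7 idealized — keep every probe's track-length dose below 1%
(image) and 0.7% (idealized) Monte Carlo uncertainty, comfortably inside
the 3.8%/2.3% precision discipline of a careful physical study, while the
full pipeline runs on one CPU in about three minutes. The reference
protocol of 1e6 decays per source voxel (≈1e9 histories, cluster scale)
remains reachable by configuration.

## TLD measurement model

The synthetic "measured" dose starts from the idealized-mode scorer dose —
the software analogue of the physical dose the chips absorb. Each chip's
raw signal is that dose divided by the reader's true calibration slope and
scaled by the relative energy response at the probe's mean photon energy
(LiF:Mg,Ti over-responds at low energies, up to ~40% relative to
high-energy reference beams), with 3% multiplicative repeatability noise.
Reduction then mirrors practice: a least-squares linear calibration fitted
to reference chips dosed at 0.25–4 Gy in a 111 keV mean-energy calibration
beam, an energy-correction factor interpolated log-linearly on the
response curve between calibration and probe energies, the 6%-of-mean
outlier flag (flagged chips are *retained*, matching the reference
protocol; no fading correction is applied), and the per-probe mean ± sd%.

The bundled response curve is plausible-shaped fixture data (labelled
synthetic in its filename), not a measured curve: no quantitative claim in
the package rests on its values, since the identical curve enters
simulation and reduction and therefore cancels up to calibration noise.
The interpolation abscissa is the fluence-weighted mean energy of the
scorer spectrum — a documented interpretation, since "mean energy of the
spectrum" admits variants (e.g. dose-weighted effective energy).

## Uncertainty budget and verdicts

Components at k = 1 (TLD chain 4.4%, energy-correction factors 0.6%,
energy interpolation 2%, setup/modeling 4%) combine in quadrature to 6.3%
(12.6% at k = 2). Following conservative practice for a first-of-kind
measurement, the adopted expanded uncertainty can be overridden — default
10% at k = 2 — and both numbers are always reported. Per-probe verdicts
compare |percent difference (measured vs image mode)| against the adopted
value, with the measured dose as reference.

## Numerical choices and degenerate inputs

* World coordinates are right-handed mm; a grid's `origin` is the center
  of voxel `[1,1,1]`; all co-registration happens through world
  coordinates, never index arithmetic.
* Voxelization uses majority vote over subsample points for materials and
  fractional apportioning for activity, rescaled so the voxelized total
  equals the nominal activity exactly; boundary voxels voted to acrylic or
  air carry no solution activity.
* The default probe layout places scorer centers 24–62 mm from the sphere
  center at staggered azimuths and heights, spanning roughly a tenfold
  photon dose range; positions are configuration, and nothing downstream
  assumes them.
* Cylinder radius 10.8 cm (standard flangeless Jaszczak); height solved
  from the 6.4 L volume. Only relative geometry matters here.
* The energy-lookup tables clamp outside 10–800 keV; CT numbers clamp to
  physical densities with a warning; empty VOIs, zero-count calibrations,
  non-positive half-lives and rank-deficient calibrations raise immediate
  errors rather than propagating NaN.
* All randomness flows from one configuration seed: scanner noise,
  calibration scan, TLD noise and each transport batch derive fixed
  offsets from it, so a rerun of the same configuration is bit-identical.

## What passing does and does not show

The suite demonstrates internal consistency of the full chain under a
faithful but idealized image-formation model: parameter recovery through
the partial-volume correction (within 5%), transport correctness against
independent oracles (analytic attenuation, equilibrium dose,
inverse-square fluence, Klein–Nishina expectations), and end-to-end
agreement of measured-style and image-based doses within the 10% expanded
uncertainty at all six probes. It does not certify any physical scanner's
recovery coefficient or calibration factor (ours differ numerically from
any specific system's), nor TLD response values, nor reconstruction
artifacts — those require the physical experiment this package is built to
rehearse.
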