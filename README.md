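# rptdose

Desk-scale, end-to-end simulation of how an image-based radiopharmaceutical
therapy (RPT) dosimetry workflow is validated against independent dose
measurements.

## The problem

Voxel-level RPT dosimetry turns a quantitative SPECT/CT scan into a 3-D
absorbed-dose map: the SPECT image supplies the activity distribution, the CT
supplies materials and densities, and a Monte Carlo engine transports the
emitted radiation. Phantom studies usually validate only the *activity*
recovery of such a chain; validating the quantity that actually matters —
absorbed dose — requires a physical dosimeter inside the phantom, typically
thermoluminescent dosimeter (TLD) chips in watertight probes.

`rptdose` reproduces that whole validation loop in software for the canonical
setup: a 16 ml hollow sphere filled with 748 MBq of I-131 inside a 6.4 L
Jaszczak-type water cylinder, with six acrylic TLD probes at staggered
distances. It is aimed at medical-physics researchers who want to rehearse,
stress-test or teach the error chain of image-based dosimetry — partial-volume
losses, calibration factors, resampling, transport physics, and
measured-dose reduction — with every stage inspectable and seeded.

## The model in brief

* **Decay bookkeeping.** `A(t) = A_admin e^{-λt}`, `λ = ln2 / T_{1/2}`
  (T½ = 8.0197 d), and the cumulated activity over an exposure window
  `Ã = (A_admin/λ)(1 − e^{−λ t_e})` [Bq·s], which scales per-history Monte
  Carlo dose to gray via `D = Ã · D_history`.
* **Image formation.** Conservative resampling to the 128³ × 4.42 mm SPECT
  grid, an isotropic Gaussian PSF (12 mm FWHM default), sensitivity ×
  duration scaling, Poisson noise; CT as a density-anchored HU volume.
* **Quantification.** Calibration factor from a uniform 5.64 L cylinder
  scan; background zeroing outside the sphere VOI; a measured recovery
  coefficient RC (apparent/true concentration) applied as a volume-level
  partial-volume correction; trilinear resampling of concentration to the
  247 × 253 × 52 × (0.977 × 0.977 × 5 mm) dose grid.
* **Dose engine.** Analog photon Monte Carlo with Woodcock tracking over the
  voxel materials, Klein–Nishina incoherent scattering, photoelectric
  absorption, 10 keV cutoff, local electron deposition; track-length fluence
  spectra and kerma-style dose estimates in 5 mm cubic scorers at the probe
  positions; batch-based uncertainties.
* **TLD reduction.** Linear reader calibration, beam-quality energy
  correction interpolated in log-energy, the 6%-of-mean outlier flag
  (flagged chips retained), per-probe mean ± sd%.
* **Agreement report.** Per-probe percent differences (measured as
  reference) against a quadrature uncertainty budget with a conservative
  expanded-uncertainty override (default 10% at k = 2).

See `vignettes/validation-methods.Rmd` for the full methods account.

## Worked example

```r
library(rptdose)

config <- run_config(seed = 1)
result <- run_pipeline(config)
print(result)
```

prints (abridged; ~3 minutes on one CPU):

```
End-to-end RPT dosimetry validation run
  administered 748 MBq, scan at 7.1 d, exposure 16.87 d
  CF 19.84 Bq/count; RC 0.842
  sphere conc: 21.18 MBq/ml raw (-16.3% vs administered), 25.16 MBq/ml corrected (-0.6%)
  cumulated activity: 5.738e+14 Bq s (ideal), 5.622e+14 Bq s (image)

 probe measured_gy measured_sd_pct image_gy image_mc_pct ideal_gy ideal_mc_pct
     1       17.05            1.59    17.95        0.300    17.18        0.207
     2       10.20            3.60    10.93        0.307    10.49        0.331
     ...
Percent difference (measured - image mode): -7.06% to 4.44%
Expanded uncertainty envelope (k = 2): 10.0%; 6/6 probes within
```

Reading it: the synthetic SPECT under-reads the sphere by 16% from
partial-volume spill-out; dividing by the measured recovery coefficient
(0.842) recovers the true concentration to −0.6%. The Monte Carlo dose from
the quantified image then agrees with the TLD-modelled measured dose at all
six probes within the 10% expanded uncertainty, which is the end-to-end
closure the physical experiment is designed to demonstrate. The worked
decay example is also a one-liner:

```r
integrated_activity(administration_record(748e6, t_exposed_days = 16.87),
                    decay_constant(8.0197))
#> <cumulated_activity> 5.738e+14 Bq s
```

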