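---
title: "Simulating long axial FOV PET with monolithic LYSO detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating long axial FOV PET with monolithic LYSO detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The study

`monopet` is a desk-scale Monte Carlo and analysis pipeline for two long
axial field-of-view (aFOV) PET scanner designs built from monolithic
50 × 50 × 16 mm LYSO detector modules on a 70 cm bore: design A with 7
detector rings (36.2 cm aFOV) and design B with 14 (72.6 cm).  The package
reproduces the NEMA NU-2 (2018) performance battery for both designs —
sensitivity, count rates / NECR / scatter fraction, spatial resolution and
image quality — together with the list-mode MLEM and TOF-MLEM
reconstruction used by the resolution and image-quality measurements.  The
numbered drivers under `analysis/` run the study stages end to end; every
computation they perform lives in package functions covered by the test
suite.

Conventions throughout: right-handed frame, z along the scanner axis,
origin at the axial and transverse centre; mm, ns, keV, Bq.  One master
seed drives all randomness through R's RNG, so every stream is
reproducible bit for bit.

## The event generator

The generator replaces a full Geant4/GATE simulation with the minimal
physics that the NEMA measures are sensitive to.  Its stages, and the
assumptions behind them:

* **Decays** are a homogeneous Poisson process at the source activity,
  uniform over the source region (line, point, or activity-weighted volume
  compartments with priority-aware rejection sampling).  Frames are short
  at *full physical activity*, so absolute singles rates — and therefore
  dead time and randoms — behave as in a long acquisition.
* **Positron physics** (`f18` mode): the annihilation point is displaced
  isotropically by an exponential mixture with mean 0.6 mm (an
  approximation of the F-18 range distribution in water; applied regardless
  of the local material), and the photon pair deviates from 180° by a
  half-normal angle of 0.5° FWHM (the literature acolinearity value in
  water).  Both are off in `back_to_back` mode, which the sensitivity
  protocol prescribes.
* **Phantom transport** is Woodcock (delta) tracking through homogeneous
  primitives with single-energy attenuation coefficients taken at 511 keV
  (water 0.0096 mm⁻¹, polyethylene 0.0093, glass 0.022, lung 0.3 × water,
  LYSO 0.087).  Interactions split into photoelectric absorption and
  Klein–Nishina Compton scattering by the material's Compton fraction;
  scattered photons keep the 511 keV coefficients, adequate down to the
  440 keV acceptance edge.  Photons terminate below 50 keV.  Rayleigh
  scattering, fluorescence, bremsstrahlung and optical transport are out of
  scope.
* **Detection**: the first flat crystal slab along the escaped photon's
  path is found analytically; the interaction depth is drawn from the LYSO
  attenuation along the chord, so the recorded position carries true
  depth-of-interaction — the defining advantage of monolithic detectors.
  With probability `p_full` the deposit is the full photon energy
  (photoelectric, or Compton with reabsorption, which large monolithic
  slabs recover for most multi-site events); otherwise a single
  Klein–Nishina electron energy is deposited and the scattered photon
  escapes (inter-module scatter is not followed).  The measured energy is
  blurred with FWHM(E) = 11.5 % · √(511·E) keV, and the timestamp is decay
  time + path/c + Gaussian jitter sized so that true pairs show a 200 ps
  FWHM coincidence time resolution.

### The one calibrated knob

`p_full` is the only free parameter of the stand-in physics.  It was
calibrated **once** against the design-A centred-line sensitivity
(29.2 kcps/MBq) and frozen at **0.707** for every other measurement, both
designs included.  Every cross-design and cross-position claim (offset /
centre ratio, design B / design A ratio, scatter fraction, NECR peak
location, resolution, CRC) is therefore out-of-sample with respect to the
calibration.

## Coincidence processing

Singles pass the 440–650 keV window, then per-module *paralysable* 300 ns
dead time (every arrival extends the dead period; throughput r·e^(−rτ)),
then sliding-window pairing with a 3 ns window opened at the first single
of each group, |t₁ − t₂| ≤ 3 ns.  Two design choices deserve an
explanation because the source material states only the model and the
values:

* **Window before dead time.**  The standard GATE digitizer chain places
  the dead-time module behind the energy thresholds.  Applying dead time to
  all interacting singles instead depresses the trues rate by ~14 % already
  at 5 kBq/mL, which contradicts the observed linearity of the trues rate
  through the clinical range.  The order is configurable
  (`dead_time_first`).
* **Multiples policy.**  `pair_coincidences()` defaults to `killAll`
  (discard any >2-single group).  The count-rate study, however, uses
  `takeAllGoods`: at the singles rates of the NECR sweep, killing pile-up
  groups costs ~9 % of trues at 5 kBq/mL and pushes the NECR peak far
  below the reported location, again contradicting the trues linearity.
  Both policies are available and logged.

Every coincidence keeps ground-truth lineage (decay ids, per-photon phantom
scatter counts), so prompts partition exactly into trues, scatters and
randoms — the same post-processing the original study applied to its ROOT
output.  No delayed-window randoms estimate is implemented.

## NEMA analyses

* **Sensitivity** (Eq. `T/(A·t)`): trues from the 5 MBq, 70 cm
  back-to-back line source, no surrounding material, at 0 and 10 cm radial
  offset; axial profiles use 1.65 mm bins of the LOR midpoint.
* **Count rates**: prompts are rebinned into SSRB sinograms (2 mm radial
  bins, 180 angles, 2 mm slices, no ring-difference limit).  The NU-2
  procedure masks |s| > 120 mm, aligns each angular projection on its
  maximum, and estimates the background under the ±20 mm peak band by
  linear interpolation between the band edges.  Slices are summed before
  the alignment by default: for a line source parallel to the axis this
  preserves the estimator and is far more robust at desk-scale counts.
  Randoms are separated using ground truth *restricted to the same 120 mm
  mask* — subtracting all randoms would bias the scatter estimate low by
  ~18 percentage points because randoms spread far outside the mask.  NECR
  = T²/(S+T+R) per point; the peak is the grid argmax (2 kBq/mL spacing
  near the peak, no curve fitting).  Headline values are sinogram-based;
  the truth-based decomposition is reported alongside.
* **Spatial resolution**: the F-18 capillary source at radii 1/10/20 cm,
  axially at the centre and at 3/8 aFOV.  LOR endpoints are blurred with an
  isotropic 1.15 mm FWHM Gaussian — the mid-point of the 1.14/1.17 mm
  positioning resolutions measured for this detector — and re-clamped into
  their 16 mm slab.  Reconstruction is list-mode MLEM, 10 iterations,
  0.5 mm voxels on a local 64³ grid around each source (the PSF is
  unchanged by the restriction; the full FOV at 0.5 mm would be ~10⁹
  voxels).  FWHM follows the NEMA profile convention: parabolic peak
  refinement, linear interpolation at the half-maximum crossings.  Sources
  sit on the +x axis so the grid axes are the radial/tangential/axial
  directions.
* **Image quality**: NEMA body phantom (torso cross-section of two 115 mm
  half-circles joined by 70 mm straight walls, 180 mm interior length),
  cold 50 mm lung insert, six hot spheres (10–37 mm) on a 114.4 mm circle
  at 4:1 or 8:1 against 5.3 kBq/mL.  Ground-truth trues are reconstructed
  — as in the source study — with TOF-MLEM (20 iterations, 2 mm voxels,
  200 ps kernel ≈ 30 mm FWHM) and attenuation correction from the
  voxelised mu-map.  CRC and background variability follow the NEMA ROI
  protocol: one sphere-sized ROI per sphere on the central slice and 60
  background ROIs per size (12 template positions × 5 slices at 0, ±1,
  ±2 cm), concentric across sizes.  The template (fixed polar positions)
  keeps every ROI ≥ 15 mm from the phantom wall and clear of the spheres
  and lung insert; the exact coordinates are a package choice since the
  standard leaves them free, and they are validated at construction.

## Reconstruction numerics

The projector is an exact radiological-path (Siddon/Amanatides–Woo) line
integral; no PSF modelling inside the reconstruction — resolution effects
live entirely in the data, as in the original processing chain.  The
sensitivity map (the MLEM normaliser) is the per-voxel detection
probability of an isotropic back-to-back pair — chord-based interaction
probability on both sides, times mu-map attenuation survival when
attenuation correction is on — evaluated on a coarse lattice (default
10 mm) and interpolated trilinearly, since it varies on centimetre scales.
MLEM starts from ones on the support of the sensitivity map, preserves
non-negativity, satisfies Σⱼ xⱼsⱼ = N after every update, and its list-mode
log-likelihood is monitored (non-decreasing on the toy problems in the test
suite).  The TOF weight is a Gaussian along the LOR centred on c·Δt/2 from
the midpoint, truncated at 3.5 σ.  Events whose forward projection is zero
(LOR misses the grid, or TOF places them outside it) are skipped and
counted.

## Problem sizes and what the reduction does (and does not) show

The original acquisitions are of order 10⁸–10¹⁰ decays; the package runs
the same protocols at 10⁶–10⁸ decays so the whole battery fits on a
desktop.  The choices per stage: sensitivity 10⁷ decays (Monte Carlo error
≈ 0.5 %), scatter fraction ~5 × 10⁵ prompts (SF error < 0.2 points), NECR
sweep ≥ 10⁵ prompts per concentration, resolution 10⁵ coincidences per
position, image quality ~4 × 10⁵ trues.  The statistical price is paid
where counts divide finely: the NECR curve is flat within a few percent
over 30–42 kBq/mL, so its grid argmax carries a ±2-step scatter, and the
per-sphere CRC at reduced counts carries several points of ROI noise with a
background variability far above the full-statistics study (variability
shrinks with acquisition time).  What passing tests show is that the
pipeline reproduces the *physics-driven* quantities (sensitivities and
their ratios, scatter fraction, sub-2 mm resolution, CRC ordering and
convergence behaviour); they do not certify absolute image-quality noise
levels at clinical statistics, nor physics the generator omits (Rayleigh,
inter-crystal scatter, LYSO intrinsic background).

## Limitations

* The crystal deposit model collapses all intra-crystal interaction
  history into `p_full`; energy spectra below the photopeak are only
  schematic.
* Flat tangent slabs leave small azimuthal gaps (40 × 50 mm of face on a
  2199 mm circumference); a curved or polygon-packed ring would differ at
  the percent level.
* Attenuation is single-energy; deep-in-window scattered photons are
  slightly over-transmitted.
* The NECR curve is reproduced in magnitude (≈0.7 Mcps for design A around
  30–40 kBq/mL) but its turnover is the least constrained output of the
  stand-in electronics: the balance between trues saturation (dead time,
  pile-up policy) and randoms growth shifts the argmax by tens of kBq/mL
  between defensible digitizer configurations, and under the shipped
  defaults the curve keeps rising to the top of the sweep range instead of
  turning over in the mid-30s.  The count-rate driver therefore reports the
  whole curve, not just the peak.
* Positron range uses a water-equivalent mixture everywhere, including
  polyethylene and lung.
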