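# monopet

Monte Carlo simulation and NEMA NU-2 (2018) performance analysis of long
axial field-of-view (aFOV) PET scanners built from **monolithic LYSO
detectors**, in R (with Rcpp cores for photon transport, coincidence
sorting and reconstruction).

## The problem

Total-body PET scanners gain sensitivity with axial length, but pixelated
crystals lose resolution to parallax at oblique angles unless they resolve
the depth of interaction (DOI). Continuous monolithic scintillator slabs
provide DOI and millimetre intrinsic resolution, which makes a *smaller*
bore and a *longer* axial FOV attractive. This package implements a
desk-scale simulation study of two such designs on a 70 cm bore, each ring
holding 40 monolithic 50 × 50 × 16 mm LYSO modules:

| | design A | design B |
|---|---|---|
| rings | 7 | 14 |
| aFOV | 36.2 cm | 72.6 cm |
| opening angle | 27° | 46° |
| detector surface | 0.70 × 10⁶ mm² | 1.40 × 10⁶ mm² |
| scintillator volume | 11.20 × 10⁶ mm³ | 22.40 × 10⁶ mm³ |

The pipeline generates list-mode events with ground-truth lineage (a
lightweight GATE stand-in: Poisson decays, positron range, acolinearity,
Woodcock transport with photoelectric/Klein–Nishina interactions, crystal
detection with DOI, energy blur and 200 ps timing), sorts coincidences
(440–650 keV window, paralysable 300 ns per-module dead time, 3 ns pairing
window), and evaluates the NEMA NU-2 measures:

* **Sensitivity** — `S = T / (A · t)` for a 5 MBq, 70 cm back-to-back line
  source;
* **Count rates** — SSRB sinograms, the NU-2 radial-mask/peak-alignment
  decomposition, `NECR = T² / (S + T + R)` and `SF = S / (S + T)`;
* **Spatial resolution** — point-spread FWHM after endpoint blurring
  (1.15 mm detector resolution) and list-mode MLEM (10 iterations, 0.5 mm
  voxels);
* **Image quality** — NEMA body phantom, TOF-MLEM (20 iterations, 2 mm
  voxels, 200 ps) with attenuation correction,
  `CRC = (C_H/C_B − 1)/(A_H/A_B − 1)` and background variability
  `N_j = SD_j / C_B` over the 60-ROI NEMA protocol.

The single free knob of the stand-in physics (the crystal full-deposit
probability, `p_full = 0.707`) was calibrated once on the design-A centred
sensitivity and then frozen; everything else follows from the geometry and
standard physics constants (see the methods vignette,
`vignettes/monolithic-lafov-pet.Rmd`).

## Worked example

```r
library(monopet)

# geometry report (the comparison-table values above)
derived_metrics(build_scanner(scanner_config("design_b")))
#> aFOV 72.6 cm | opening angle 46 deg | surface 1.40 x10^6 mm^2 | volume 22.40 x10^6 mm^3

# NEMA sensitivity of design A, centred line source, 10^7 decays
st <- sensitivity_study("design_a", radial_offset = 0, n_decays = 1e7, seed = 1)
st$result
#> sensitivity 29.11 kcps/MBq (T = 291105, A = 5 MBq, t = 2 s, offset 0 mm)

# scatter fraction of the NEMA scatter phantom at low activity
scn <- scenario_scatter("design_a", 0.045)
sim <- run_simulation(scn, n_decays = 5e7, seed = 1, max_decays = 1e8)
pc  <- process_coincidences(sim)
truth_count_rates(pc$coincidences, sim$duration_s)$sf
#> [1] 0.3119
```

At the same seeds the full battery gives: design A 29.11 kcps/MBq at the
centre and 27.57 at 10 cm offset, design B 102.90 kcps/MBq (a 3.5-fold
gain from doubling the aFOV); scatter fraction 31.1 % (ground truth) vs
30.6 % (NU-2 sinogram estimate); all radial/tangential/axial PSF FWHM at
the six NEMA point-source positions between 1.18 and 1.26 mm — flat,
sub-2 mm resolution across the FOV thanks to DOI; and a NECR curve with trues
linear through the clinical range (within 3 % at 5 kBq/mL) and a broad
plateau of ≈ 0.7 Mcps over 30–50 kBq/mL — the turnover concentration is
the least constrained output of the stand-in coincidence electronics (see
the methods vignette).

The study itself lives in `analysis/01_geometry.R` …
`analysis/05_image_quality.R`, thin numbered drivers that print what they
find and write tables under `results/`.

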