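---
title: "Liquid-scintillator electron-beam dosimetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liquid-scintillator electron-beam dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A vessel of alcohol-based liquid scintillator (AbLS — 2-ethoxyethanol and
water with trace PPO/bis-MSB fluors) glows blue where a clinical electron
beam deposits energy. A consumer camera photographing that glow therefore
records a two-dimensional map of absorbed dose, and the depth at which the
glow dies away measures the beam's practical range — the quantity that
radiotherapy quality assurance checks against the machine's nominal energy.
This package implements the full analysis chain around that idea:

1. material constants of the scintillator (effective atomic number, mean
   excitation energy, electron density);
2. electron stopping powers and CSDA ranges;
3. a condensed-history Monte Carlo scoring a depth x lateral dose grid;
4. colorimetric decomposition of photographs (CIE XYZ, HSV) and V-cut
   segmentation into a relative dose map;
5. practical-range extraction from depth-dose curves;
6. optical tomography of a rotating sample (sinogram + filtered
   back-projection);
7. synthetic-data generators that stand in for the camera and the LINAC, so
   every stage runs and is tested offline.

## Material model

`compose_mixture()` turns molecular formulas and proportions into elemental
mass fractions. The 7:3 scintillator ratio is interpreted as a **volume**
ratio with component densities 0.930 (2-ethoxyethanol) and 0.998 (water)
g/cm^3 — the common convention for mixing solvents — and the bulk density is
pinned to the measured 0.945 g/cm^3 rather than the ideal-mixing estimate
(0.950). The fluors, present at grams per litre, are neglected. Under this
convention:

```{r}
library(scintdose)
abls <- abls_material()
effective_atomic_number(abls)   # 6.77
mean_excitation_energy(abls)    # 68.9 eV
```

The effective atomic number uses the Mayneord power law with
electron-number-fraction weights, `Zeff = (sum_i alpha_i Z_i^m)^(1/m)` with
`m = 2.94`, the standard photoelectric-regime exponent in medical physics;
`m` is an argument, not a constant. The mean excitation energy uses Bragg
additivity over the ICRU-37 **condensed-phase** constituent values (H 19.2,
C 81, N 82, O 106 eV). The condensed-phase set is the one under which
additivity reproduces the accepted I of liquid water (about 75 eV); with
gas-phase elemental values the same formula lands near 69 eV for water,
which is why the distinction matters at the 2 eV level of interest here.

## Stopping powers and CSDA ranges

Collision stopping power is the relativistic Bethe formula with the Møller
stopping number. The density-effect correction is evaluated **exactly** in
Sternheimer's oscillator picture: each element contributes its subshells
(occupancy, binding energy), the oscillator frequencies are scaled by a
common factor so the material's ln I is reproduced, and the dispersion
equation is solved numerically at each energy. We chose the exact evaluation
over the usual x0/x1 parameterized fit after finding the fit leaves the
collision stopping power about 1% high across 2–12 MeV — enough to push the
CSDA ranges 1.4% off, with a 2% total error budget. Against the standard
water tables the implementation agrees to about 0.1% at 1 and 10 MeV.

Radiative (bremsstrahlung) loss uses the rule-of-thumb proportionality
`S_rad = S_col (E + me c^2) Zeff / Phi`. The calibration constant `Phi` is
fixed once so that water's radiative stopping power at 10 MeV equals the
ICRU-37 value (0.1813 MeV cm^2/g). Below ~12 MeV the radiative term is a
few-percent correction; its residual shape error (the true radiative loss
grows slightly faster than linearly with E) leaves the CSDA ranges about
0.4% below the reference tables, which is inside the target precision.

`csda_range()` integrates `dE/S_tot` on a log grid (200 points per decade,
trapezoid rule) from a 1 keV floor; the sub-floor residual (< 1 mg/cm^2) is
taken as zero. Halving the grid spacing moves the result by < 0.1%.

For AbLS this yields specific CSDA ranges of 3.03, 4.48 and 5.87 g/cm^2 at
6, 9 and 12 MeV, i.e. 3.20, 4.74 and 6.21 cm after dividing by the density.

## Monte Carlo transport

`simulate_electron_beam()` is a class II condensed-history walk:

* **Step size**: 2% fractional energy loss per step (configurable). Each
  step's continuous energy deposit is spread uniformly along the step —
  depositing at a fixed fraction of the step would alias the common energy
  grid of all histories into stripes on the depth grid.
* **Multiple scattering**: Gaussian polar deflection per step with the
  Highland/Rossi width, using the mixture radiation length from the standard
  elemental approximation. The log term is evaluated per step and floored at
  0.25.
* **Delta rays**: Møller knock-on electrons above the 100 keV transport
  cutoff are produced explicitly (simplified 1/T^2 spectrum, kinematic
  emission angle) and transported as secondary histories; the continuous
  loss is restricted consistently, so the mean total loss still equals the
  Bethe value by construction. *This branch is on by default*: without it
  (class I, no energy-loss straggling) the distal falloff of the depth-dose
  curve is too steep and the practical ranges come out 4–6% short of both
  the published values and of what a full-physics code produces; with it
  they agree to about 1%. `deltas = FALSE` restores the class I scheme,
  which is also the configuration (together with `scattering = FALSE` and
  on-track radiative deposit) in which the walk collapses to deterministic
  slowing-down and reproduces the CSDA range to one cell — the main
  consistency check between the transport and the quadrature.
* **Radiative loss** is tracked as escaped energy by default (the photons
  leave the vessel at these energies); `radiative = "deposit"` deposits it
  on-track. Energy is conserved exactly: deposited + escaped equals the
  injected energy to rounding.
* **Scoring** is depth x lateral with the third axis integrated out — the
  same projection a camera performs. The 6 x 6 cm field overhangs the 5 cm
  vessel width, so histories entering outside the liquid are counted as
  escaped immediately, as in the experiment.

The photon mode samples exponential free paths from a Klein–Nishina
attenuation coefficient (plus a small parameterized photoelectric term),
draws the Compton energy transfer by Kahn's rejection method, hands the
electron to the condensed-history engine at the kinematic angle, and lets
the scattered photon continue with the deflected direction. A monoenergetic
2 MeV source stands in for the clinical 6 MV bremsstrahlung spectrum, whose
head model is out of scope; the mode exists to reproduce the qualitative
photon behaviour (dose throughout the vessel, no finite range).

## Practical-range extraction

`practical_range()` implements the clinical tangent construction: the depth
where the tangent at the steepest point of the distal falloff meets the
flat bremsstrahlung background. Numerical choices: the steepest point is
located on a 3-cell moving average (the tangent itself is fitted to the raw
data); the tangent window defaults to 20% of the falloff extent, measured
between the 80% and 20% crossings and rescaled to the full drop; the
window is applied in grid indices, which makes the extraction exactly
equivariant under uniform depth rescaling (pixel-calibration changes); on
flat linear falloffs the steepest-point tie is broken at the middle of the
tied stretch with a relative tolerance, so float jitter cannot select a
corner. The background is the mean over the last 10% of the grid. The
quoted uncertainty is half the Rp spread when the tangent window is varied
+/-50% — a documented convention, since the experiment's +/-0.30 cm error
bars have no stated model.

The tangent construction is an extrapolation: its intersection can land a
fraction of a percent beyond the CSDA range when the falloff toe curves
(the published 12 MeV values show the same inversion, 6.28 cm projected vs
6.23 cm CSDA). The physical penetration-depth bound applies to the dose
itself, not to Rp.

`refraction_correct()` rescales the apparent depth axis by a single
user-supplied factor (default 1 = off). The camera-side refraction mapping
depends on unmodelled geometry, so the package does not guess it; the
synthetic camera can inject a known compression (`depth_scale`) to exercise
the correction end to end.

## Colorimetry and the image pipeline

Camera JPGs are gamma-encoded; `srgb_decode()`/`srgb_encode()` implement
the IEC 61966-2-1 transfer. XYZ uses the sRGB/D65 matrix (cameras emit
sRGB), with chromaticity x+y+z = 1 wherever the tristimulus sum is
positive. HSV is the hexcone model computed **on the encoded values** by
default — that is what common image tooling does and what the published
V-cut levels (0.3 electron, 0.6 photon) refer to; `linearize = TRUE` gives
linear-light HSV.

`dose_map_from_image()` separates the two roles of V: the *mask* comes from
the encoded V (V >= v_cut, matching the published procedure), while the
*dose amplitude* on kept pixels is recovered in linear light, because
fluorescence intensity is proportional to dose before the camera's gamma.
Without the linearization the recovered map is a gamma-compressed monotone
distortion of the dose — fine for segmentation, wrong for a quantitative
round trip. `linear_dose = FALSE` restores the raw-V behaviour.

## Synthetic data: the stated world

`render_fluorescence_image()` models the camera as: normalized dose ->
gain -> optional apparent-depth compression -> blue-dominant linear RGB
(default emission direction maps to z-dominant chromaticity) -> Gaussian
PSF (sigma 1.5 px) -> container-glare bands (encoded V level 0.3 by
default, 0.25 in the electron presets so the published 0.3 cut removes
them) -> Poisson/Gaussian noise (sigma 0.01 linear) -> sRGB encoding ->
8-bit quantization. Noise-off renders invert to the input dose up to
quantization; that is the round-trip the tests assert at r > 0.999.

The gamma-style preset places a nearly uniform exponentially attenuated
glow (encoded V 0.64–0.70) between dark margins with glare bands at V =
0.3 — the configuration that produces the double-peaked V histogram whose
populations the 0.6 cut separates.

The rotation rig renders the T-bar-in-vial phantom analytically: circle
chords and ray/rectangle clipping give exact line integrals per column, so
the generator is an independent path from `forward_radon()` (which
interpolates a raster); frames store transmitted intensity `exp(-OD)`. The
refraction perturbation is an even function of the detector coordinate
(rays bend symmetrically about the vial axis), which is exactly the class
of artifact that 360-degree sampling suppresses by averaging opposing
views — the mechanism behind the 360-vs-180 comparison.

What the generators do **not** emulate: lens distortion, vignetting,
rolling shutter, JPEG compression artifacts, raw-sensor Bayer processing,
and the LINAC head (bremsstrahlung spectrum, flattening filter). A green
test therefore establishes the correctness of the analysis chain on
camera-like inputs, not the calibration of any particular camera.

## Tomography

`forward_radon()` uses per-angle bilinear sampling; mass is conserved
across angles to 0.1% for extended objects. `inverse_radon_fbp()` filters
in the frequency domain (Ram-Lak default, Shepp-Logan and Hann variants,
zero-padded to the next power of two) and back-projects with linear
interpolation; the discrete scale factor is pi/n_angles, with full-circle
data double-covering the half-circle integral so the same factor applies.
Reconstruction is masked to the inscribed circle. Coverage below 180
degrees is refused. Angles are assigned as
`(frame index mod period) * 360 / period` and repeated revolutions are
averaged — the frames-to-angle bookkeeping the experiment left unstated.

## Tolerances and degenerate inputs

* compositions must sum to 1 within 1e-9; chromaticity closure is 1e-6;
  the HSV round trip is exact to 1e-9 on a 10^3 color grid;
* energy bookkeeping in the MC is exact to 1e-9 relative;
* all-zero dose grids, monotone (photon-like) depth-dose curves, empty
  V-masks, mixed-size frame stacks and sub-180-degree sinograms raise
  informative errors rather than returning numbers;
* every stochastic stage takes an explicit seed and is bit-reproducible.

## Known limitations

* The stopping-power module targets 1e-2 to 1e2 MeV electrons; no shell or
  Barkas corrections, no heavy particles.
* The radiative parameterization is linear in E; its ~0.4% CSDA bias is
  documented above and accepted.
* The photon source is monoenergetic; photon depth-dose curves are
  qualitative.
* The condensed-history walk has no spin/Mott corrections and treats
  multiple scattering as a single Gaussian deflection per step; ranges and
  build-up are accurate at the percent level, backscatter fractions are
  not targeted.
* Image file I/O (PNG/JPG) is not included; the pipeline consumes in-memory
  arrays, and the generators produce them. Dose grids, curves, sinograms
  and tables round-trip through plain-text CSV/JSON.
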