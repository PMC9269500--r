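# scintdose

Radiotherapy quality assurance needs a fast check that an accelerator's
electron beams penetrate as far as their nominal energy says they should. A
vessel of alcohol-based liquid scintillator (AbLS — 2-ethoxyethanol : water
7:3 with trace fluors, density 0.945 g/cm³) glows blue where the beam
deposits energy, so a single photograph of the glow is a two-dimensional
dose map, and the depth where the glow dies off measures the beam's
practical range. `scintdose` implements that analysis end to end, for
medical physicists and for anyone building camera-based dosimetry:

* **Material constants** — elemental composition of mixtures, effective
  atomic number `Zeff = (Σ αᵢ Zᵢᵐ)^{1/m}` (electron-fraction weights,
  m = 2.94), mean excitation energy by Bragg additivity
  `ln I = Σ wᵢZᵢ/Aᵢ ln Iᵢ / Σ wᵢZᵢ/Aᵢ`, electron density.
* **Stopping powers and ranges** — Bethe–Møller collision stopping power
  with an exact Sternheimer (oscillator-model) density-effect correction,
  a calibrated radiative term, and the CSDA range `R = ∫ dE / S_tot(E)`.
* **Monte Carlo** — class II condensed-history electron transport (Highland
  multiple scattering, explicit Møller delta rays, 100 keV cutoff) scoring
  a depth × lateral dose grid in the scintillator vessel; a simplified
  Compton/Klein–Nishina photon mode.
* **Colorimetry** — sRGB transfer, CIE XYZ/xyz decomposition, hexcone HSV,
  V histograms, V-cut segmentation, and relative dose maps from
  photographs.
* **Range analysis** — the clinical practical range `Rp`: the intersection
  of the tangent at the steepest distal falloff of the percent-depth-dose
  curve with the bremsstrahlung background; plus R50, the depth of maximum,
  pixel calibration and a refraction correction.
* **Tomography** — sinograms from rotating-sample frame stacks, forward
  Radon projection, filtered back-projection (Ram-Lak/Shepp-Logan/Hann).
* **Synthetic data** — a camera model (blue emission, PSF, container glare,
  sensor noise, sRGB, 8-bit) and an analytic rotating T-bar phantom, so the
  whole pipeline runs and is tested without a LINAC or a camera.

## Worked example

Material constants and CSDA ranges (`analysis/01`, `analysis/02`):

```r
library(scintdose)
abls <- abls_material()          # 7:3 by volume, density pinned to 0.945
effective_atomic_number(abls)    # 6.773
mean_excitation_energy(abls)     # 68.94 eV
sapply(c(6, 9, 12), csda_range, comp = abls)
# 3.0261 4.4767 5.8677 g/cm^2  ->  / 0.945 = 3.20 4.74 6.21 cm
```

The three-way range comparison (`analysis/03_range_study.R`, here at
30 000 histories per energy; ~1e5 for production):

```
 energy_MeV csda_gcm2 csda_cm rp_mc_cm rp_image_cm rp_image_unc_cm zmax_mc_cm
          6     3.026   3.202    3.125       3.116           0.005      1.925
          9     4.477   4.737    4.689       4.678           0.017      2.875
         12     5.868   6.209    6.220       6.203           0.015      3.525
```

Per energy: the CSDA range (the no-scatter upper scale), the practical
range extracted from the Monte Carlo depth-dose curve, and the practical
range recovered from a synthetic fluorescence photograph of that same dose
grid after V-cut segmentation at 0.3 — the camera route reproduces the MC
range to a few hundredths of a cm. `zmax > 0` is the build-up: dose rises
to a sub-surface maximum before falling off.

Optical tomography (`analysis/04_tomography.R`):

```
reconstruction residual vs truth (NRMSE in the inscribed circle):
  360-degree sinogram: 0.1704
  180-degree sinogram: 0.2229
unperturbed reference: NRMSE 0.0778
```

With a refraction-style perturbation on the rotating-vial frames,
full-circle sampling averages opposing views and reduces the artifact
relative to half-circle sampling; without perturbation the filtered
back-projection sits at its discretization floor.

## Acceptance script

`scripts/acceptance.R` recomputes the pipeline's headline quantities from
scratch — the Monte Carlo practical ranges at 6/9/12 MeV (1e5 histories),
the AbLS effective atomic number and mean excitation energy, and the
image-pipeline range at 6 MeV — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The seed drives every stochastic stage; the run takes about 90 seconds on
one CPU.
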