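#!/usr/bin/env Rscript
# Optical tomography of the rotating T-bar-in-vial phantom: render the frame
# stack, assemble the optical-density sinogram from the baseline row, and
# reconstruct by filtered back-projection — once from the full 360-degree
# data and once from the first 180 degrees — against the rasterized truth.
# A refraction-style detector perturbation (even in the detector coordinate)
# emulates the vial's optics; full-circle sampling averages opposing views
# and reduces the artifact.

library(scintdose)

spec <- rot_phantom_spec(
  phantom = t_bar_phantom(),
  n_frames = 480, frames_per_rev = 240,   # two revolutions, averaged
  width = 160, height = 48, baseline_row = 24,
  refraction_strength = 3, noise_sd = 0.004, seed = 11L
)
study <- run_tomo_study(list(spec = spec, out_dir = "results/tomo_study"))

print(study)
cat(sprintf("\nreconstruction residual vs truth (NRMSE in the inscribed circle):\n"))
cat(sprintf("  360-degree sinogram: %.4f\n", study$residual_360))
cat(sprintf("  180-degree sinogram: %.4f\n", study$residual_180))
cat("\nfindings: the hole rectangles and the bar/vial boundaries are recovered;\n")
cat("the refraction perturbation leaves streaks that double sampling (360\n")
cat("degrees) suppresses relative to single sampling (180 degrees).\n")

# a clean reference run without optical perturbation
clean <- run_tomo_study(list(spec = rot_phantom_spec(
  n_frames = 240, frames_per_rev = 240, width = 160, height = 48,
  baseline_row = 24)))
cat(sprintf("\nunperturbed reference: NRMSE %.4f (the FBP discretization floor)\n",
            clean$residual_360))
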