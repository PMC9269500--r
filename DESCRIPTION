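Package: scintdose
Title: Liquid-Scintillator Electron-Beam Dosimetry and Optical Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for alcohol-based liquid-scintillator (AbLS)
    dosimetry of clinical electron beams. Computes mixture material properties
    (effective atomic number, mean excitation energy), electron collision and
    radiative mass stopping powers with an exact Sternheimer density-effect
    correction, and CSDA ranges; simulates electron and photon beams with a
    condensed-history Monte Carlo scoring two-dimensional percent depth dose;
    decomposes fluorescence photographs into CIE XYZ and HSV representations
    and extracts relative dose maps by V-thresholding; extracts practical
    ranges from depth-dose curves by the tangent/background intersection rule;
    and reconstructs optical tomography slices from rotating-sample frame
    stacks by filtered back-projection. A synthetic-data module emulates the
    camera and the rotation rig so every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
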