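Package: veneclipse
Title: Venous Artefact and Inverted-Voxel Correction for Retinotopic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and correcting the effect of venous artefact
    ("venous eclipses") on population receptive field (pRF) based retinotopic
    maps of human visual cortex, with an emphasis on area hV4. Implements the
    four classic mapping stimuli (rotating bowtie, expanding ring, drifting bar,
    full-field flash) as binary aperture movies, canonical haemodynamic response
    modelling, two-stage coarse-to-fine pRF fitting, Fourier travelling-wave
    phase maps, normalised mean maps, correlation-sign classification of
    positive and inverted voxels, the time-course flipping correction,
    discrimination of inverted voxels from negative BOLD responses, visual-field
    quadrant coverage and completeness classification, a polar-angle map
    smoothness statistic, and cortical-depth-resolved analyses. Includes a
    seeded synthetic cortical-patch generator that injects venous eclipses,
    inverted voxels and negative BOLD responses for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
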