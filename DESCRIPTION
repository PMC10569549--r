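Package: hivemorph
Title: Volumetric Segmentation and Morphometry of Bee Brain Micro-CT Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for large-scale volumetric analysis of
    insect brain micro-CT data: synthetic phantom generation with realistic
    cohort statistics, denoising and automatic cropping, patch-based 3D U-Net
    semantic segmentation of six neuropils (implemented natively on BLAS),
    island removal and left/right splitting of paired neuropils, volumetric
    morphometry, and the population statistics used in comparative bee
    neuroanatomy (volume variation, allometry, colony effects, lateralization),
    with Dice and average symmetric surface distance evaluation validated
    against brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    lme4,
    RNifti,
    tiff,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse
Config/testthat/edition: 3
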