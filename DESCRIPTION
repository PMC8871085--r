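Package: clipkeep
Title: Metal-Preserving Bone-Subtraction CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bone-subtraction CT angiography (BS-CTA) removes bone by
    voxelwise subtraction of a non-contrast head CT from a co-registered
    contrast-enhanced CTA, but aneurysm clips and coils appear in both
    scans and are subtracted away with the bone. clipkeep locates metallic
    implants on the non-contrast volume by global Hounsfield-unit
    thresholding, builds a rectangular region of interest around each
    connected component, refines the metal mask inside each region with
    Otsu's between-class-variance threshold, and re-incorporates the metal
    voxels into the subtracted volume. The package also provides the
    matching evaluation metrics (Dice similarity coefficient, directed and
    bidirectional Hausdorff distance, summary statistics with t-based
    confidence intervals), a synthetic head-phantom generator with exact
    ground-truth masks, NIfTI and basic DICOM-series input, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
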