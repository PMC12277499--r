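Package: petquant
Title: Quantitative PET/CT SUV Analysis with Organ Masks, Lesion
    Delineation and a Transformer Segmentation Backend
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts PET voxel data to body-weight standardized uptake
    values (SUV) from acquisition metadata with radioactive decay
    correction, transfers CT-defined organ masks onto the PET grid by
    resampling and optional rigid mutual-information registration,
    computes whole-organ and fixed-radius spherical VOI SUV statistics,
    delineates lesions at fractional-SUVmax thresholds with total lesion
    glycolysis and cumulative SUV histograms, and provides a synthetic
    dual-grid phantom generator plus a desk-scale Swin-UNETR-style 3D
    segmentation backend for end-to-end testing. Reads and writes DICOM
    series (explicit VR little endian) and NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
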