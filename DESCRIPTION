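Package: amypvc
Title: CT- and MRI-Based Partial Volume Correction and SUVR Quantification
    for Amyloid PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partial volume correction (PVC) for amyloid PET images using
    tissue probability maps derived from a structural scan (CT or MRI):
    resolution matching of probability maps to the PET point spread function,
    white-matter nonspecific-binding subtraction, division by the smoothed
    gray-matter probability map, and standard uptake value ratio (SUVR)
    images referenced to the median of an eroded cerebellar volume of
    interest. Includes cross-modality slope (alpha) correction, voxelwise and
    per-VOI group statistics, a digital head phantom generator with known
    ground truth for validation, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
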