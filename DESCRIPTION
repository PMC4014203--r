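Package: rtverify
Title: Delivery Verification Analysis for Radiotherapy Dose Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance of intensity-modulated
    and volumetric-arc radiotherapy: gamma-index comparison of planned versus
    delivered or reconstructed dose distributions (2D planar and 3D volumetric,
    global and per-structure), dose-volume-histogram deviation metrics including
    the homogeneity and conformity indices, and per-detector gantry-angle
    response correction for 2D ion-chamber arrays. Includes a synthetic phantom
    and nasopharyngeal-carcinoma-like plan generator so that every analysis
    stage can be exercised end-to-end against known ground truth, plus readers
    and writers for DICOM RT Dose / RT Structure Set and plain-text planar-dose
    exchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
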