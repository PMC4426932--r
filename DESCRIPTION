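Package: gacqa
Title: Gantry-Angle-Corrected Dose Prediction QA for Step-and-Shoot IMRT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific quality assurance for step-and-shoot IMRT with
    multileaf collimator (MLC) abutment corrections that depend on gantry
    angle.  Builds composite electronic portal imaging device (EPID) non-gap
    test images, computes per-abutment pixel-value ratios and their
    reproducibility, fits the linear pixel-ratio-to-dose-ratio calibration,
    derives per-gantry-angle correction (GAC) lookup tables, injects the
    corrections into per-beam 2D measured-vs-planned error maps,
    back-projects the error maps onto per-beam 3D dose grids, and evaluates
    predicted dose distributions with gamma analysis, dose-difference and
    distance-to-agreement maps, and dose-volume histogram indices.  Includes
    seeded synthetic generators for every input so the whole pipeline is
    testable without clinical data, plus minimal readers and writers for
    DICOM RT Dose and plain-text dose planes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
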