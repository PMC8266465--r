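Package: ginqams
Title: Single-Marker Quantification and Annotation of Ginsenosides from
    UPLC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for targeted quantification of Panax ginsenosides from
    high-resolution LC-MS data: synthetic run generation with known truth,
    extracted-ion-chromatogram peak integration with signal-to-noise
    estimation, external-standard calibration with S/N-based detection and
    quantification limits, single-marker quantification (QAMS) via averaged
    relative response factors against an internal marker, comparison of the
    two quantification routes by the standard method difference, and
    rule-based MS/MS annotation of glycosides through glycosidic
    neutral-loss decomposition, aglycone classification and isomer grouping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
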