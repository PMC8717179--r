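Package: abdecomp
Title: Decomposition of the Amyloid-PET Signal into Fibrillar and
    Nonfibrillar Plaque Source Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-modal analysis pipeline for preclinical amyloid-PET
    studies in mouse models of cerebral amyloidosis. Standardizes PET
    SUV ratios against wild-type controls (z-scores), pairs longitudinal
    PET observations with cross-sectional immunohistochemistry estimates
    of fibrillar and nonfibrillar beta-amyloid plaque coverage by age and
    genotype, fits a nested ladder of least-squares models with bootstrap
    confidence intervals, and decomposes the in vivo PET signal into
    fibrillar and nonfibrillar contribution shares, including validation
    of fitted coefficients on independent cohorts. Includes a seeded
    synthetic-cohort generator with known ground truth so the full
    pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
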