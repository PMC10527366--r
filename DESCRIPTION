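Package: dejpro
Title: Dermo-Epidermal Junction Protrusion Quantification and PRO Grading
    for LC-OCT Skin Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects and measures downward protrusions of the dermo-epidermal
    junction (DEJ) on vertical-slice (B-scan) skin images such as those
    produced by line-field confocal optical coherence tomography (LC-OCT),
    grades images and lesions on the ordinal PRO I-III scale used for actinic
    keratosis, and evaluates the agreement between automated and expert
    grades with contingency tables, linearly weighted Cohen's kappa, rank
    correlations and Welch tests. A seeded phantom generator produces
    ground-truthed surface/DEJ contour pairs, speckled B-scan-like images and
    simulated rater cohorts so the whole pipeline can be validated without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    png,
    rmarkdown,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
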