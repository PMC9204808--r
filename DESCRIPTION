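Package: ppscreen
Title: Suspect and Non-Target Screening of Co-Formulants in Plant
    Protection Products by LC-HRMS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hybrid suspect-screening and unknown-analysis pipeline for
    identifying and quantifying co-formulants (surfactants, solvents,
    preservatives, dispersants) in marketed plant protection products from
    centroided LC-HRMS data (full-scan MS1 plus data-dependent MS2).
    Provides exact-mass chemistry (formula algebra, adduct and
    fragment-cation m/z, isotope-pattern simulation, accurate-mass formula
    enumeration), mzML input/output, a synthetic-run generator with known
    ground truth, extracted-ion-chromatogram feature detection with
    signal-to-noise and peak-shape quality control, suspect-database
    matching with isotope and ddMS2 fragment verification under Schymanski
    confidence levels, ethoxylate homolog-series detection,
    standard-addition quantitation with SANTE-style validation metrics,
    and risk flagging of banned co-formulants against the 0.1 percent w/w
    threshold and oral reference doses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse,
    withr
Config/testthat/edition: 3
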