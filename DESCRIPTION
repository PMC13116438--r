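Package: wbequant
Title: Isotope-Dilution Quantitation and Consumption Back-Calculation for
    Wastewater-Based Drug Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A standardized computational workflow for wastewater-based
    epidemiology of substance use. Takes targeted LC-MS/MS peak-area exports
    for a multi-drug analyte panel through isotope-dilution calibration,
    signal-to-noise based limit-of-detection and limit-of-quantitation
    decision rules, quality-control batch gating, solid-phase-extraction
    spike-recovery evaluation, and back-calculation of population-normalized
    excretion and consumption rates from site flow and population data.
    Includes a seeded synthetic-batch generator so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
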