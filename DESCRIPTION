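Package: drugtally
Title: Configurable Drug-Count Measures from Pharmacy Refill Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counts the number of drugs a patient uses from pharmacy refill
    claims under a three-component framework: scope (which products qualify as
    drugs), uniqueness (product- versus ingredient-based de-duplication at four
    key levels), and timeframe (cross-sectional index-gap rules, post-index
    rescue fills, cabinet-supply carry-over, hospitalization adjustment, and
    per-drug overrides). Ships fifteen preset measures, a claims preprocessing
    layer, cohort-level percentile and change-from-reference analytics, a
    seedable synthetic claims generator for sensitivity analysis, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
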