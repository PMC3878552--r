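Package: extractaudit
Title: Concordance Auditing of Binary Outcome Data Extraction Across
    Systematic Reviews
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies variable-level discrepancies in binary
    outcome data extracted by multiple systematic reviews of the same
    randomised trials, and quantifies the impact of those discrepancies on
    pooled treatment-effect estimates. Ships a worked corpus of three
    overlapping reviews of hip arthroplasty for displaced intracapsular hip
    fracture, a DerSimonian-Laird random-effects relative-risk meta-analysis
    engine with a Mantel-Haenszel fixed-effect cross-check, a sensitivity
    layer that detects significance flips between reviews, and a synthetic
    corpus generator that plants typed extraction errors (denominator
    transposition, numerator recalculation from rounded percentages) and
    selection differences (alternative trial arm, timepoint, or analysis
    population) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
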