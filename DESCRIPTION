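Package: pvsignal
Title: Pharmacovigilance Signal Detection for FAERS-Style Spontaneous
    Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis workflow for disproportionality-based adverse
    event signal detection in spontaneous reporting databases shaped like
    the FDA Adverse Event Reporting System (FAERS). Reads "$"-delimited
    quarterly ASCII file sets (DEMO, DRUG, REAC, THER, INDI, OUTC plus a
    deleted-case list), deduplicates cases by the highest-primaryid rule,
    selects target-drug cases by name and primary-suspect role, maps
    MedDRA preferred terms to system organ classes through a pluggable
    dictionary, and computes reporting odds ratios with Woolf confidence
    intervals, proportional reporting ratios with Pearson chi-squared,
    and observed-to-expected (EBGM-style) ratios with one-sided lower
    bounds, including age-restricted subgroup sweeps. Time-to-onset
    intervals from therapy start to event date are tabulated and fitted
    with a maximum-likelihood Weibull model whose shape parameter
    classifies the hazard as early, random, or wear-out failure. A
    synthetic report generator with planted drug-event associations makes
    the whole pipeline testable without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
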