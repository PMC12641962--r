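Package: brca2triage
Title: Prioritization and Cohort Analysis of Germline BRCA2 Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for triaging germline BRCA2 variants found in hereditary
    breast/ovarian cancer cohorts. Parses HGVS protein and cDNA nomenclature,
    maps residue positions onto annotated functional domains (BRC repeats,
    DNA-binding domain), derives categorical calls from SIFT and PolyPhen-2
    scores at configurable cutoffs, reports qualitative physicochemical
    changes for missense substitutions (residue volume, hydropathy, charge),
    and combines these evidence channels in a stepwise Low/Moderate/High
    prioritization rubric with a full audit ledger. Also provides exact-test
    comparison of carrier counts against reference cohorts and population
    databases, descriptive and carrier-stratified cohort statistics, and a
    seeded synthetic-cohort generator so the whole pipeline is testable
    without patient-level data.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
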