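Package: rorscreen
Title: Disproportionality Screening of Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on Individual Case
    Safety Report (ICSR) line listings. Classifies reports into named adverse
    drug reaction categories (antimicrobial resistance, drug ineffectiveness,
    off-label use) via configurable MedDRA Preferred Term catalogs, produces
    the standard descriptive surfaces (demographics, System Organ Class
    frequencies, category rates and distributions, unfavourable-outcome
    breakdowns), and screens drug pairs for disproportionate reporting with
    the reporting odds ratio (ROR), Woolf log-normal confidence intervals and
    the EMA signal rule (at least 5 cases and CI lower bound above 1). A
    seeded synthetic ICSR generator with exact-count allocation, including a
    preset emulating an aggregated EudraVigilance extract for the five
    Reserve-group cephalosporins, makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
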