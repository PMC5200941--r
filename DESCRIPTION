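Package: trialaudit
Title: Automated Audit of Clinical Trial Results Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An audit engine for clinical trial results transparency.
    Parses clinicaltrials.gov-style registry records, applies trial-level and
    sponsor-level eligibility filters, links eligible trials to candidate
    results publications by registry identifier (secondary-source accession or
    title/abstract mention), screens candidates with the validated PubMed
    therapy clinical-query filters, and aggregates per-trial dissemination
    verdicts into sponsor and sponsor-class rankings of unreported trials.
    Includes a synthetic corpus generator with planted ground truth so the
    whole pipeline is testable offline, plus a command-line interface and
    deterministic JSON/CSV exporters for dashboard data feeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    vctrs,
    tibble,
    dplyr,
    purrr,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
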