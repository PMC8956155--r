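Package: labequity
Title: Workload Equity, Activity-Based FTEs and Turnover Signals for
    Laboratory Sign-Out Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores case-level pathology sign-out records under a
    declarative workload-point tariff (L4E-style points, fee units, block
    and case counts), derives activity-based full-time equivalents from
    distinct ISO signing weeks, assigns pathologists to hospital groups by
    yearly case mix, and quantifies workload inequality via the Gini
    coefficient, Lorenz curve and Hoover index. Computes the "Robin Hood
    FTE" redistribution that equalizes per-FTE workload across groups and
    detects significant-absence-or-departure (SAD) events from year-over-
    year drops in signing weeks. Includes a seedable synthetic-laboratory
    generator with a ground-truth ledger for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
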