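Package: hipcea
Title: Markov Cohort Cost-Effectiveness Model of Hip Fracture Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annual-cycle Markov cohort model comparing surgical and
    nonoperative treatment of displaced intracapsular and extracapsular hip
    fractures in patients 65 years and older. Tracks state occupancy under
    age-specific natural mortality scaled by post-fracture relative risks,
    accumulates lifetime costs by category (direct medical, long-term medical,
    nursing home, home modification) and quality-adjusted life years, and
    reports incremental savings, QALY gains, ICERs and dominance. Includes
    one-way sensitivity sweeps, threshold (breakeven) solving on the
    nursing-home utilization rate, scenario analyses, national extrapolation
    to the annual US fracture cohort, a Gompertz-Makeham synthetic life-table
    generator, and an independent individual-level microsimulation used to
    validate the cohort engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
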