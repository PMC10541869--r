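Package: kapsim
Title: Simulation of the Deceased-Donor Kidney Allocation Process
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discrete-event simulation framework for deceased-donor kidney
    allocation. Couples a dynamic candidate waiting list (Poisson arrivals and
    exit-risk-ranked Poisson departures), a configurable two-tier
    national/state allocation rule with ABO-strict and ABO-compatible rounds
    and an optional state-balance mechanism, risk-based eligibility filters
    built on EPTS and KDPI percentiles (cut-off and interval longevity
    matching), and a stochastic shared decision-making model of organ-offer
    acceptance. Includes a synthetic cohort generator with configurable
    marginal distributions, parallel replication with reproducible
    substreams, and an allocation-characteristics comparison suite
    (Hellinger distance, Kolmogorov-Smirnov statistic, kurtosis, stratified
    median log-ratios) for validating simulated against observed allocations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
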