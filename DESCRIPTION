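Package: threathazard
Title: Discrete-Time Hazard Models and Simulated Avoidance in Uncertain Threat Anticipation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the temporal statistics of uncertain threat
    anticipation at one-second resolution. Represents discrete threat
    schedules (the probability mass of shock time over a trial), derives
    survival, hazard-rate and cumulative-hazard profiles, and constructs
    condition pairs whose marginal threat probability is matched over a
    window while their hazard rates are dissociated. Includes a synthetic
    cohort generator in which agents learn a schedule from unavoidable
    shocks and then trade escape against per-second earnings, and an
    analysis battery for the resulting trial records: Kaplan-Meier curves
    of escape with shock censoring, log-rank tests, epoch-wise avoidance,
    earnings comparisons, rating-hazard association via a two-stage
    summary-statistics model, forced-choice and rank-sum tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
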