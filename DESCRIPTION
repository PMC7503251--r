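Package: erppi
Title: Emergency Room Process Performance Indicators from Clinical Event Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes process performance indicators for emergency room (ER)
    clinical processes from event logs, organised along the devil's quadrangle
    (time, cost, quality, flexibility). Includes an event-log data model with
    CSV and XES input/output, preprocessing remedies for common data
    imperfection patterns (inadvertent time travel, form-based event capture,
    collateral events, exclusive cases), length-of-stay and cycle-time
    indicators, resource workload profiles, an earth-mover's-distance matching
    rate against a stochastic reference language, triage quality metrics for
    the Korean Triage and Acuity Scale (KTAS), directly-follows graphs with
    performance annotations, dotted-chart exports, and a discrete-event
    simulator of ER logs with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
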