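Package: akival
Title: Validation Toolkit for Laboratory Acute Kidney Injury e-Alert Algorithms
Version: 1.0.0
Authors@R: person("Kit", "Harper", email = "kit.harper@example.org",
    role = c("aut", "cre"))
Description: Tools to audit the consistency of acute kidney injury (AKI)
    e-alerts submitted by clinical laboratories against a central
    re-implementation of the NHS England creatinine-based detection
    algorithm. Provides a deterministic staging engine with the extended
    365-day look-back (reference values RV1/RV2, 48-hour delta rule,
    high-creatinine escalation), chance-corrected inter-rater agreement via
    weighted Gwet AC1 with ordinal weights and Landis-Koch interpretation
    bands, a synthetic registry simulator with configurable laboratory
    corruption models (alert suppression, stage miscoding, missing monthly
    files), and an end-to-end study pipeline producing overall, per-laboratory,
    per-LIMS, sensitivity and subgroup agreement reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
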