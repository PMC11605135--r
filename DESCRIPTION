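Package: mammoscreen
Title: Simulation of AI-Integrated Double-Reading Mammography Screening
Version: 0.1.0
Authors@R:
    person("Screening", "Simulation Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates population-scale breast cancer screening under
    standard radiologist double reading with arbitration and under three
    AI-integrated workflows: AI replacing the first reader, AI replacing
    the second reader, and stand-alone AI triage into low-, moderate- and
    high-risk bands. Provides a synthetic-cohort generator with correlated
    readers and class-conditional AI score mixtures, threshold-selection
    procedures (specificity matching and dual-constraint triage search),
    workload accounting, and paired diagnostic-accuracy statistics
    (Clopper-Pearson intervals, McNemar tests, and a generalized score
    test for predictive values in paired designs).
License: MIT + file LICENSE
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
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
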