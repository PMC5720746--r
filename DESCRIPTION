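Package: dxpath
Title: Diagnostic-Pathway Resource Utilization and Budget Impact Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse resource utilization in a diagnostic care pathway
    from patient-level cohort data. Estimates per-modality usage rates with beta
    posteriors, tests between-hospital independence of usage, costs the pathway
    through a state-transition model against a tariff table, propagates rate
    uncertainty by probabilistic sensitivity analysis, and audits guideline
    adherence (over- and underutilization) together with its budget consequence.
    Ships a synthetic two-hospital lung-cancer cohort generator so the full
    pipeline is reproducible without access to registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
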