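Package: stentcua
Title: Cost-Utility Markov Modelling of Ureteral Stents in Malignant
    Ureteric Obstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A four-state monthly Markov cohort model comparing a metallic
    (Resonance) ureteral stent with standard polyurethane double-J (JJ)
    stents for palliative management of malignant ureteric obstruction,
    from a UK NHS provider perspective.  Implements constant-hazard
    transition-probability derivation (rate conversion, pooled incidence,
    Kaplan-Meier constant-hazard fitting, life-table mortality blending),
    scheduled stent exchanges, discounted cost and QALY accrual with
    half-cycle correction, ICER and net monetary benefit, deterministic
    (tornado) and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, scenario analysis, a
    patient-level microsimulation validation oracle, and a reporting
    pipeline with YAML/JSON configuration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
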