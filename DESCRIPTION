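Package: crcscreen
Title: Markov Cohort Modelling of Colorectal Cancer Screening Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic Markov state-transition cohort model of the
    colorectal adenoma-carcinoma sequence for evaluating organized screening
    programs. Implements the natural history of adenoma onset, progression to
    advanced adenoma and preclinical cancer (UICC I-IV), symptomatic and
    screen detection, stage- and detection-mode-specific survival, and a
    surveillance state machine for post-polypectomy follow-up. Compares
    annual stool-test strategies (FIT, gFOBT) and 10-yearly colonoscopy
    against no screening, reporting life-years gained, averted cases and
    deaths, positive test results, colonoscopy complications, lifetime
    costs, incremental harm-benefit ratios and an incremental
    cost-effectiveness frontier with (extended) dominance. Includes
    hierarchical natural-history calibration to incidence and stage
    distribution targets (Nelder-Mead within basin-hopping), deterministic
    one-way/two-way/scenario sensitivity analyses, and a synthetic-data
    generator for life tables, survival tables and calibration targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2,
    withr
Config/testthat/edition: 3
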