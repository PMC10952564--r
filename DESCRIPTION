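Package: donorecall
Title: Discrete Event Simulation of Personalized Blood-Donor Recall Strategies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Individual-level discrete event simulation of whole-blood donor
    recall over a one-year horizon, comparing the current fixed inter-donation
    intervals (16 weeks for women, 12 for men) with personalized intervals
    driven by a linear post-donation hemoglobin-recovery model. Includes a
    synthetic donor-population generator, the recovery model with a
    threshold-crossing interval solver and a mixed-effects fitting routine,
    five recall policies (fixed recall, medium/high certainty post-donation
    testing, early recall, and limited on-site testing), per-event
    blood-service costing, per-1000 outcome summaries with interval-band
    distributions, bootstrap uncertainty intervals, and a first-return
    internal-validation mode.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
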