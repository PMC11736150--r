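Package: taviwait
Title: Microsimulation of Risk-Based Prioritization for TAVI Waitlists
Version: 0.1.0
Authors@R: person("taviwait", "developers", role = c("aut", "cre"),
    email = "taviwait@example.org")
Description: Individual-level weekly-cycle simulation of a closed cohort of
    patients referred for transcatheter aortic valve implantation (TAVI).
    Synthetic patients carry heterogeneous 12-week predicted risks of death,
    hospitalization and urgent-procedure conversion; they are classified into
    risk tiers, assigned tier-specific wait-times under a fixed-capacity
    budget constraint (constant cohort-mean wait), and followed under
    Weibull time-escalating hazards until death or procedure. Includes
    calibration of hazard multipliers to registry count targets, a scenario
    grid over tier sizes and wait-times with common-random-number relative
    risks, wait-time benchmark selection under a cap on the non-prioritized
    tier, heatmap-table reporting, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
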