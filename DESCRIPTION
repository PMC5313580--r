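Package: riskselect
Title: Measuring Risk Selection in Regulated Health-Insurance Markets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for regulators and health-economics researchers to measure
    risk selection in competitive health-insurance markets with risk
    equalization and premium-rate restrictions. Implements risk-equalization
    model fitting and residual-expense accounting, group compensation
    statistics (under/overcompensation, predictive ratios, reduction versus no
    equalization), overrepresentation indices, naive per-insurer residual
    means, and the efficiency-unconfounded switcher estimator of selection
    based on the residual expenses of plan switchers in the years adjacent to
    the switch. A synthetic two-year market simulator with known ground-truth
    insurer efficiency and selection strength supports validation of every
    estimator by parameter recovery.
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
    withr
Config/testthat/edition: 3
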