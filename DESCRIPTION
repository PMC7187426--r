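Package: vaplan
Title: Vitamin A Intervention Planning for Young Children
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates child dietary intake surveys, estimates usual vitamin A
    intake distributions from repeated 24-hour recalls, overlays fortification
    and supplementation programs to compute reach and effective coverage,
    links coverage to vitamin-A-preventable child deaths, costs program
    portfolios over a ten-year horizon, finds cost-minimising portfolios under
    national coverage constraints, traces region-level policy pathways for
    withdrawing vitamin A supplementation under staged validation rules, and
    quantifies robustness of the optimal portfolio by Monte Carlo simulation.
    Calibrated to the three-macroregion structure (North, South, Cities) used
    in national micronutrient planning for Cameroon.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
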