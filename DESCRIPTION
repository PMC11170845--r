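Package: mgppk
Title: Population Pharmacokinetics and Dose Optimization of Intravenous
    Magnesium Sulfate in Preeclampsia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One-compartment intravenous-infusion population-pharmacokinetic
    modelling of magnesium sulfate given for seizure prophylaxis in
    preeclampsia. Provides an analytic concentration model with superposition
    over multi-day loading/maintenance schedules, FOCE-type nonlinear
    mixed-effects estimation with covariate models on clearance and volume,
    stepwise covariate selection by likelihood-ratio thresholds,
    goodness-of-fit, nonparametric bootstrap and visual-predictive-check
    diagnostics, and Monte Carlo dose optimization via probability of target
    attainment for the 2-3.5 mmol/L therapeutic window. A synthetic-study
    generator emulating the observed design makes every stage runnable and
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    ggplot2
Config/testthat/edition: 3
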