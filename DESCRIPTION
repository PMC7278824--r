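Package: oxikin
Title: Kinetic Analysis of Bio-Oil Autoxidation from Oxygen-Uptake Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining kinetic parameters of thermal bio-oil
    autoxidation from headspace oxygen-consumption measurements. Provides a
    mechanistic radical-chain simulator of inhibited and uninhibited lipid
    peroxidation (stiff ODE integration with re-aeration bookkeeping),
    closed-form steady-state rate expressions, extraction of the induction
    period and of the initial and steady oxygen-uptake rates from
    multi-segment traces with Type A/B/C oil classification, estimation of
    the initiation rate by propyl gallate standard addition, composition-based
    regression models of the steady oxidation rate and of the antioxidant
    effect, a blend-stability predictor, and seeded synthetic-data generators
    so the whole pipeline is testable without laboratory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    sandwich,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
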