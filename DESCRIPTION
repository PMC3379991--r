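Package: markovcea
Title: Markov Cohort Cost-Effectiveness Model of Cetuximab in Recurrent or
    Metastatic Head and Neck Cancer
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monthly-cycle Markov cohort state-transition model comparing
    cetuximab plus platinum-based chemotherapy with platinum-based
    chemotherapy alone in first-line treatment of recurrent or metastatic
    head and neck squamous cell carcinoma, from a Canadian public-payer
    perspective (2011 CAD). Time-dependent transition probabilities are
    derived from parametric survival stand-ins calibrated to published
    Kaplan-Meier anchors, with life-table background mortality, a
    calibrated progression-to-death stream, and year-3 extrapolation.
    Includes half-cycle-corrected discounted cost/QALY/life-year
    valuation and the ICER, deterministic one-way/two-way/threshold and
    horizon sensitivity analyses, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, and expected value of
    perfect information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
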