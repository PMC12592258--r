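Package: lazdose
Title: Genotype-Guided Lazertinib Dosing by Population Pharmacokinetic Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form steady-state pharmacokinetic engine and Monte Carlo
    virtual-patient simulator for evaluating GSTM1 genotype-guided lazertinib
    dosing regimens. Calibrates a two-compartment oral population model to
    published steady-state exposure summaries (geometric means and coefficients
    of variation of trough and average concentrations), simulates virtual
    cohorts under once-daily and every-other-day regimens, and computes
    geometric mean ratios with bioequivalence-style verdicts, probability of
    attaining an efficacy trough threshold, and annual drug-cost comparisons.
License: MIT
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
    deSolve,
    ggplot2,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
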