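Package: icdcea
Title: Cost-Utility Model of Implantable Cardioverter-Defibrillators in Heart Failure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision tree plus annual-cycle Markov cohort model comparing an
    implantable cardioverter-defibrillator (ICD) on top of optimal
    pharmacological therapy (OPT) against OPT alone for NYHA class II-III
    heart failure, from a health-system perspective. Provides parameter
    handling with beta/uniform sampling distributions, a synthetic Gompertz
    background-mortality life table, differential discounting of costs and
    QALYs, incremental cost-effectiveness ratios, net monetary benefit,
    break-even device pricing, one-way/tornado deterministic sensitivity
    analysis, and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
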