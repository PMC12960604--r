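Package: itpcea
Title: Cost-Utility Modelling of Thrombopoietin Receptor Agonists for
    Chronic Immune Thrombocytopenia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid decision-tree and four-state Markov cohort model for
    cost-utility analysis of second-line thrombopoietin receptor agonists
    (hetrombopag, eltrombopag, avatrombopag) in adult chronic immune
    thrombocytopenia from the Chinese healthcare-system perspective.
    Includes parametric survival extrapolation of duration of response with
    AIC/BIC model selection, incremental net-monetary-benefit economics,
    one-way deterministic sensitivity analysis with tornado ranking,
    probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves, scenario analyses, and a synthetic-data module
    generating the inputs (life table, pseudo individual-patient data)
    that are not publicly available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
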