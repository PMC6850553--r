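Package: genentry
Title: Pharmacopeial Monograph Standards and Generic Drug Competition
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the association between pharmacopeial
    drug-product monograph standards and generic drug competition.
    Reads drug approval records (FDA Orange Book products dialect or CSV),
    a monograph directory and a drug-year sales panel; links them at the
    ingredient-route market level through an auditable eligibility cascade;
    fits three cluster-robust estimands of the monograph effect (a logistic
    model for any generic entry, a Cox gap-time model for the interval
    between successive generic approvals, and a log-link count model for
    the number of generic manufacturers, all with sandwich variance over
    therapeutic classes); and propagates the fitted rate ratio through a
    counterfactual competition-to-price engine to estimate yearly cost
    savings. A synthetic-cohort generator with known ground truth makes
    every stage testable without proprietary sales data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    jsonlite,
    optparse
Config/testthat/edition: 3
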