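Package: irnvrules
Title: Credal Decision-Tree Rule Mining for Injury-Severity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mines decision rules for the causes of fatal injury in urban
    traffic accidents of novice drivers. Implements three decision-tree split
    criteria - the classical information-gain ratio, the imprecise info-gain
    based on the imprecise Dirichlet model, and the approximate nonparametric
    predictive inference criterion - together with a maximum-entropy solver
    over probability-interval credal sets, the information root node variation
    (IRNV) tree ensemble, C4.5-style fractional handling of missing values,
    and support/probability rule selection. Includes a synthetic generator for
    DGT-style categorical accident records with planted antecedent-to-fatal
    rules so the full pipeline is testable without the original microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
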