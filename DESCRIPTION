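Package: phedkit
Title: Covering Rough-Set Rule Learning and Prospect-Theory Decision
    Support for Public-Health Emergencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-attribute public-health emergency decision
    analysis. Implements covering rough-set attribute reduction via the
    family method (effective approximation blocks, related families,
    discernibility-function reducts), a cost-aware greedy decision rule
    extraction algorithm (A-DRE) operating on the hypergraph of related
    families, decision-rule induction with support and coverage, and
    ordered-rule classification. Also provides an interval (grey)
    cumulative-prospect-theory model for ranking emergency response
    schemes evaluated on gain and cost criteria over multiple time
    frames, and consensus-based aggregation of prospect matrices across
    multiple departments. Seeded synthetic generators emulate decision
    tables with planted reducts and grey evaluation matrices so every
    stage is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
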