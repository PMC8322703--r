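Package: cernaflow
Title: Integrative Rank-Aggregation Discovery of circRNA-miRNA-mRNA
    Regulatory Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns multiple case/control expression microarray datasets into
    robust differentially expressed genes via the Robust Rank Aggregation
    order-statistic score, identifies hub genes in a confidence-filtered
    protein-protein interaction network with a ten-centrality ensemble
    (MCC, DMNC, MNC, Degree, EPC, BottleNeck, EcCentricity, Closeness,
    Radiality, Betweenness) re-aggregated with the same statistic, detects
    dense network complexes with an MCODE implementation, and assembles a
    circRNA-miRNA-mRNA competing-endogenous-RNA network by three-database
    target intersection, direction-constrained miRNA validation, and a
    circRNA coverage filter. Ships seeded synthetic-data generators with
    planted ground truth so every stage and the end-to-end pipeline are
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
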