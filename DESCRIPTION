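Package: mirScore
Title: Multi-Database Evidence Scoring and Ranking of miRNAs Against a Gene Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Aggregates experimentally validated and computationally predicted
    miRNA-target interaction evidence over a fixed gene panel into a validated
    score (V-Score), a prediction score (P-Score) and a combined consensus
    score (C-Score), and ranks candidate miRNAs for therapeutic prioritization.
    Includes confidence-tier filtering and degree summaries for STRING-style
    protein-protein interaction edge lists, relative-expression quantification
    of qPCR data by the 2^-ddCt method with ANOVA/Tukey group statistics and a
    Lilliefors normality check, MTT viability normalization, and seeded
    synthetic-data generators with planted ground truth for end-to-end testing.
    Ships example evidence tables for a seven-gene atherosclerosis drug-target
    panel (PCSK9, HMGCR, MTTP, APOC3, LPA, CETP, APOB).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
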