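Package: mirffl
Title: Feed-Forward Loop Analysis of Integrated TF-miRNA Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing integrated gene regulatory networks that
    combine transcription factor-target (TTI), transcription factor-miRNA (TMI)
    and miRNA-target (MTI) interactions, and for analysing their structure.
    Includes ChIP peak-to-gene assignment via strand-aware binding windows,
    compilation of miRNA-target sets from dual predictor output with degradome
    support, a three-node motif census (feed-forward and feedback loops) with
    permutation-null Z-score enrichment, party/date hub classification from
    clustering coefficients and GO-term similarity, hierarchical layer
    decomposition of the TF-miRNA core network, and synthetic-data generators
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    withr,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
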