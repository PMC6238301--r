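Package: promclust
Title: Consensus Biclustering of Promoter ChIP-Seq Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds normalized promoter-by-experiment matrices of ChIP-seq
    peak heights, defines promoters and their activity status from TSS
    annotations and tiered CAGE peaks, and sorts the matrix with a robust
    consensus biclustering procedure: repeated sparse-SVD (or k-means plus
    t-test) base runs matched to a target clustering by linear assignment,
    with frequency filtering, row association and per-row Welch t-test bars.
    Also included: combinatorial regression feature selection with
    hypergeometric variable enrichment, motif-hit reduction to best hit per
    promoter, promoter-anchored chromatin-loop analysis with enhancer-state
    classification, and a synthetic-data generator with known ground truth
    that exercises every rule end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
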