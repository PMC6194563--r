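Package: pathcover
Title: Greedy Set-Cover Reduction of Redundancy in Pathway Gene-Set Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consolidated pathway databases contain heavily overlapping gene
    sets, which inflates and complicates downstream analysis. pathcover
    implements greedy set-cover algorithms that select a reduced, non-merged
    subset of pathways covering a chosen fraction of the genes in a
    collection, with three scoring rules (standard uncovered-gene count,
    size-controlling proportional score, and rarity-weighted hitting-set
    score), a p-value-ordered set-cover filter for pathway-enrichment
    results, redundancy metrics (overlap score, reduction percentage,
    Jaccard distributions, size statistics, source composition), GMT
    input/output, and a synthetic-collection generator for benchmarking.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
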