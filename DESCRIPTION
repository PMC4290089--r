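Package: synloss
Title: Discovery of Lineage-Specific Syntenic Gene Losses from Ortholog Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies protein-coding genes missing from a focal lineage by
    side-by-side alignment of one-to-one ortholog tables from reference
    genomes, clusters the losses into conserved syntenic deletion blocks
    under span and gene-count criteria, re-verifies blocks after re-ordering
    by a second reference genome, and characterises the result: chromosomal
    clustering via goodness-of-fit chi-squared tests, paired block-size
    comparisons, flanking-block rearrangement classification, and
    functional-annotation enrichment against block-structure-matched
    permutation nulls with Benjamini-Hochberg false discovery control.
    Includes a seeded simulator of multi-species ortholog tables with
    planted deletion blocks, rearrangements and planted term enrichments
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
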