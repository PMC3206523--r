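Package: seedscreen
Title: Digital Differential Display and Microarray Screening for Seed-Specific Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screen for genes specifically expressed in the
    developing cereal seed. Combines digital differential display (DDD) of
    pooled EST library counts -- Fisher's exact test on 2x2 pool tables with
    a pool-fraction and fold-enrichment selection rule -- with a microarray
    organ-specificity filter (cross-hybridizing probeset exclusion,
    replicate averaging, a strict linear-scale fold rule, Pearson profile
    neighbors and Pearson hierarchical clustering), unigene-level
    intersection of the two screens, hypergeometric GO-term enrichment, and
    cross-species replication metrics over a percent-identity-binned
    homology map. Includes a synthetic-data generator that emulates
    multinomial EST sampling, replicated log2 expression panels, partial
    homology maps and sparse GO annotation, with planted seed-specific
    genes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
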