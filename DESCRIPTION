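Package: islandmark
Title: Window-Based ChIP-Seq Island Calling with Dual Controls and
    Direct-Target Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies enriched islands in ChIP-seq tag data with a
    Poisson background model, gap-tolerant window aggregation and
    Benjamini-Hochberg false discovery rate control against one or more
    control samples (input DNA and/or a knockout ChIP).  Annotates called
    islands against a promoter/exon/intron/intergenic partition of the
    genome, computes average tag-density metaprofiles around reference
    points and along percentile-scaled gene bodies, performs interval-set
    overlap accounting (for example CpG-island and H3K4me3
    colocalization), and integrates binding with WT/knockout expression
    fold changes into a direct-target gene list.  Includes a synthetic
    data generator (toy genomes, tag sets with planted enrichment,
    negative-binomial expression pairs with planted fold changes) so the
    whole pipeline is testable against a known truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    dplyr,
    tibble,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
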