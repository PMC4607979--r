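Package: medipscape
Title: Comparative MeDIP-Seq DNA Methylation Analysis Across Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bin-level analysis of MeDIP-seq methylation enrichment across
    populations or breeds: genome tiling into fixed-width bins, read counting
    and depth-normalized enrichment scoring, CpG-island detection by the
    observed/expected CpG ratio, promoter/exon/intron annotation, differential
    methylated region (DMR) calling by pairwise t-tests with fold-change
    filters, breed-specific DMR sets, gene mapping and hypergeometric gene-set
    enrichment, hierarchical clustering of methylation profiles, haplotype
    Fst with permutation tests, and qPCR delta-delta-Ct expression integration.
    Includes a synthetic-data generator that emulates a multi-breed MeDIP-seq
    study design so that every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
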