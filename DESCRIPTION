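Package: ClonalHybrids
Title: Clonality, Hybridization, and Karyotype Analysis for Black Yeast Population Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of strictly clonal fungi
    that form stable, highly heterozygous diploid intraspecific hybrids.
    Implements ploidy classification from assembly statistics, linkage
    disequilibrium decay curves with a half-maximum readout, aneuploidy
    calling from median-normalized sequencing-depth windows, detection of
    copy-neutral and deletion-driven loss of heterozygosity from
    heterozygous-SNP windows, per-region distance trees with multilabeled
    leaves for hybrid subgenomes, cross-region concordance scoring,
    grouping of diploids into hybridization events, and habitat/geography
    enrichment tests with Monte-Carlo Fisher p-values. A synthetic-data
    generator produces clonal populations with planted hybridization
    events, aneuploid segments, and loss-of-heterozygosity tracts with
    full ground truth, so every stage of the pipeline can be exercised
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    phangorn,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
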