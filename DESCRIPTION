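Package: methTiles
Title: Tile-Based Differential Methylation, Chromatin Occupancy and
    Allele-Specific Analysis for Germline Epigenomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of DNA methylation and chromatin occupancy on
    non-overlapping 500-bp genomic tiles, as used to study methylation loss in
    Dnmt3a/Dnmt3b-deficient male germ cells and its chromatin consequences in
    sperm and hybrid two-cell embryos. Provides tiling and annotation of a
    genome (CpG counts, GC content, blacklist removal), aggregation of per-CpG
    methylation counts to tiles with assay-specific filters, a beta-binomial
    likelihood-ratio test for differential methylation with
    Benjamini-Hochberg correction, classification of hypomethylated DMRs into
    six developmental trajectory groups, log2-RPKM quantification with fast
    cyclic-loess normalization and negative-binomial differential occupancy
    testing, SNP-based maternal/paternal read assignment for hybrid crosses,
    Fisher exact class-enrichment statistics, binned signal profiles around
    tile centers, and negative-binomial differential expression with a
    natural-spline pseudotime covariate. Seeded synthetic-data generators with
    truth tables make every stage testable without deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    splines,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
biocViews: DNAMethylation, DifferentialMethylation, ChIPSeq, Epigenetics,
    Sequencing, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
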