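Package: dualmark
Title: Polymorphic SNP, InDel and SSR Marker Discovery Between Two
    Resequenced Cultivars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable, fully tested pipeline for genome-wide discovery and
    characterization of polymorphic DNA markers between two resequenced
    cultivars of the same species.  Detects perfect microsatellites (SSRs)
    under per-motif minimum-length rules with class I/II categorization,
    applies depth/quality/allele-read confidence filters to SNP calls,
    classifies cross-cultivar InDel and SSR length polymorphisms, annotates
    markers against GFF3 gene models (CDS, UTR, intron, intergenic) with
    synonymous/nonsynonymous calls for coding SNPs, and computes genome-scale
    summaries (per-chromosome densities, 100-kb window tracks,
    transition/transversion ratios, motif and InDel length spectra).  A
    diversity module computes per-locus Na, Ho, He and PIC from a multi-sample
    SNP genotype panel and builds a neighbor-joining dendrogram from a binary
    allele-presence similarity matrix.  A synthetic-data module generates
    reference genomes, diverged cultivar pairs and genotype panels with a
    planted-truth ledger so every stage is testable against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    digest,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
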