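Package: estpoly
Title: EST Marker Discovery: SSR Mining, Indel Detection and Multi-Sample SNP Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for discovering candidate molecular markers in de novo
    assembled transcriptome (EST) contigs sequenced from a panel of genotype
    samples. Mines perfect microsatellites (SSRs) under motif-class repeat
    thresholds and merges near-adjacent loci into compound repeats; detects
    indels between per-genotype consensus sequences in gapped alignments and
    flags those overlapping SSR loci as candidate polymorphic SSRs; calls
    biallelic SNPs from multi-genotype read pileups through a filter cascade
    (allele depth, average coverage, flanking length, a Bayesian site-quality
    posterior, and absolute isolation), classifying each site per genotype as
    intra-sample monomorphic or polymorphic and tabulating transitions versus
    transversions. A seeded synthetic-data generator plants SSR, SNP and indel
    truth sets so every stage is verifiable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    rtracklayer,
    SummarizedExperiment,
    BiocGenerics,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
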