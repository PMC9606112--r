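Package: sexlinker
Title: Reference-Optional Detection of Sex Chromosomes from K-mer and
    Pool-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects sex chromosomes and sex-determining regions from
    short-read data of male and female pools (or single individuals),
    with or without a reference genome. Implements canonical k-mer
    counting with a minimum-occurrence cutoff, sex-specific k-mer set
    algebra (subtraction, subsampling, multi-species core intersection),
    placement of k-mers on a reference with per-linkage-group
    enrichment and differentiated-block calling, cross-species shared
    k-mer tables for inferring the polarity of sex-chromosome turnover,
    pooled FST and XY/ZW-patterned SNP classification from
    Popoolation2-style sync files or pileup text, and genome-windowed
    log2(XY:ZW) rank statistics (Kruskal-Wallis, Dunn's post-hoc with
    Benjamini-Hochberg correction, per-chromosome median rank). A
    pool-seq simulator with planted sex-determining regions provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
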