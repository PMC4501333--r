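Package: poliiscan
Title: Slope-Based Annotation of Stage-Specific RNAPII Enhancers from ChIP-Seq Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates RNA polymerase II (RNAPII) enhancers from ChIP-seq
    coverage by detecting paired rising/falling slope regions in binned,
    masked, smoothed unique-stack-height profiles; clusters features by
    differential occupancy across culture conditions; screens enhancer
    windows for hybrid (C/EBP-ATF4) versus canonical C/EBP motifs; computes
    hypergeometric co-occupancy enrichment and anchored density matrices;
    and analyses in vitro cistromics protein titrations with RPM thresholds.
    A fully deterministic synthetic-data generator (genome, mappability,
    condition-structured read stacks, titration series, ground-truth tables)
    drives end-to-end validation without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
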