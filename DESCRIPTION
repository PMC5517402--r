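Package: circleaf
Title: Circular RNA Profiling Across the Leaf Lifespan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for studying circular RNAs (circRNAs)
    over a developmental time course of plant leaves. Classifies
    back-splice junctions against a genome annotation into exonic,
    intronic and intergenic categories, quantifies circRNA expression
    with pseudocount-per-million normalization, calls differentially
    expressed circRNAs over stage windows of a 14-point time course,
    tests independence from host-gene expression, scores plant-style
    miRNA target sites on mRNAs and circular sequences, and assembles
    circRNA-miRNA-mRNA sponge networks gated by fold change and
    expression anti-correlation. Includes a synthetic-data generator
    that emulates the structure of a leaf lifespan RNA-seq experiment
    so the full pipeline can be exercised without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    methods,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
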