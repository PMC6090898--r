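Package: bactx
Title: Coverage-Based Operon Reconstruction, Differential Expression and
    cre-Site Prediction for Bacterial Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for comparative bacterial RNA-seq analysis:
    reconstruction of operons and transcript boundaries from strand-specific
    per-base coverage, RPKM normalization with a negative-binomial exact test
    for differential expression, resampling-based functional-category
    enrichment, and weight-matrix scanning for catabolite-responsive element
    (cre) sites with exact p-values and promoter assignment. A synthetic-data
    generator with known ground truth makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
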