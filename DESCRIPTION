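Package: crescan
Title: Classification of Cis-Regulatory Elements from Histone-Mark
    Coverage with Compact Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting promoters and enhancers
    (including active and poised states) from histone-mark ChIP-seq
    alignments. Builds labeled, binned, RPM-normalized coverage tensors over
    promoter/enhancer/background regions; calls active versus poised states
    by K-means clustering of GRO-seq coverage; trains compact convolutional
    or recurrent classifiers with class-balanced sampling and plateau
    learning-rate scheduling; scans the genome with sliding windows and
    consolidates filtered predictions into element blocks; and interprets
    first-layer convolutional filters via singular value decomposition of
    their activations. Includes a synthetic-data generator that plants
    class-specific histone-mark signatures on a toy genome so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    pROC,
    withr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
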