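Package: afselex
Title: Peak Calling, Grading and Binding-Site Length Prediction for
    Aptamer-Free SELEX-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analyzes aptamer-free SELEX-seq (afSELEX-seq) experiments, in
    which sheared genomic dsDNA is iteratively selected for binding to a
    protein of interest and every cycle is sequenced. Builds per-cycle
    genome frequency (coverage) tracks from SAM or BLASTn tabular
    alignments, identifies peaks in the final enrichment cycle with a
    sliding-window scan thresholded against the unselected control cycle,
    grades peaks by round-weighted inter-cycle enrichment, predicts
    binding-site length from peak width, and exports peak sequences,
    "spoof" background peaks and zero-order Markov background models for
    downstream motif discovery. Includes a synthetic afSELEX-seq data
    simulator with ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    withr,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
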