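Package: wrapseq
Title: Nucleosome Wrapping State Analysis from Paired-End Fragment Lengths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies nucleosome wrapping states from paired-end MNase or
    MNase-ChIP fragment lengths. Computes the nucleosome wrapping score
    NRS(X) = (a - b)/(a + b) and its genome-wide z-score, the nucleosome
    wrapping index (NRI), over a binned genome; segments the NRI track into
    tight and loose nucleosome wrapping domains (TiNRD/LoNRD); computes
    replication-timing tracks from four S-phase fraction libraries with
    quantile normalization; provides sequence-composition diagnostics of
    MNase cut-site bias; and ships a synthetic-data generator with known
    ground truth for end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
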