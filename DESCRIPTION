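Package: srnamir
Title: Small RNA-Seq miRNA Discovery, Annotation and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of small RNA sequencing libraries from a
    control versus Dicer-like knockout design, as used to study miRNA
    biogenesis in the green alga Chlamydomonas reinhardtii: raw-read quality
    and adapter filtering into counted clean tags, tag annotation against
    contaminant non-coding-RNA and known-miRNA references and the genome,
    hairpin-based novel miRNA discovery with miRNA/miRNA* duplex evaluation
    under Dicer/DCL cut-site geometry, stem-loop re-classification of
    previously reported miRNAs into precursor classes, TPM normalization with
    fold-change and significance testing between groups, and 2^-ddCt
    RT-qPCR quantification. Ships a synthetic-data generator that plants
    hairpin loci with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
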