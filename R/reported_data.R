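#' Published down-regulated miRNA quantifications (dcl1 mutant study)
#'
#' The published quantification table of the 22 miRNAs significantly
#' down-regulated in a *Chlamydomonas reinhardtii* dcl1 insertional mutant
#' relative to the wild-type strain CC-5325 (sRNA-seq, n = 3 per group):
#' mature sequence, genomic location, group mean TPM values and the reported
#' log2 fold change, split into the high-differential
#' (log2 fc <= -1) and medium-differential (-1 < log2 fc <= -log2 1.5)
#' tiers. Used as a worked-example input for the fold-change and tier
#' arithmetic of the expression stage.
#'
#' @return A `data.frame` with one row per down-regulated miRNA (multi-locus
#'   entries flattened to their first reported locus).
#' @export
reported_downregulated_mirnas <- function() {
  path <- system.file("extdata", "dcl1_downregulated_mirnas.tsv",
                      package = "srnamir", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
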