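#' qPCR Ct validation set
#'
#' Ct values for nine experimentally validated rsRNA:target pairs measured
#' across four human cell lines (A549, MDA-MB-231, HeLa, MCF7), together
#' with the reference Pearson correlation reported for each pair. Ct is inversely
#' related to abundance, so an rsRNA repressing its target shows a negative
#' Ct:Ct correlation across cell lines. One gene value (ATM in MCF7) is
#' missing, exercising pairwise-complete handling.
#'
#' @return List: `ct` (tibble: `id` + one Ct column per cell line) and
#'   `pairs` (tibble: `srna`, `gene`, `published_pcc`).
#' @export
#' @examples
#' ex <- qpcr_ct_example()
#' ct_correlation_table(ex$ct, ex$pairs)
qpcr_ct_example <- function() {
  dir <- system.file("extdata", package = "rsrnakit")
  list(ct = read_table_tsv(file.path(dir, "qpcr_ct.tsv"), required = "id"),
       pairs = read_table_tsv(file.path(dir, "qpcr_pairs.tsv"),
                              required = c("srna", "gene")))
}

#' Reference genomic annotation counts of discovered rsRNAs
#'
#' Per-class locus annotation counts for a discovery set of 11,234 rsRNAs
#' (the class counts sum slightly above the total because multi-locus sRNAs
#' can carry several classes).
#'
#' @return List: `counts` (named numeric) and `total_n`.
#' @export
#' @examples
#' a <- annotation_class_example()
#' summarize_annotation(a$counts, a$total_n)
annotation_class_example <- function() {
  list(counts = c("repeat" = 5078, "ncRNA" = 680, "intergenic" = 73,
                  "intron" = 5324, "exon" = 99),
       total_n = 11234)
}
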