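# Gene-model helpers: spliced transcript sequences, transcript-space
# coordinates of annotated regions, and projection of transcript intervals
# back onto the genome through the exon structure.

# Exons of one gene in transcript order (5' -> 3' of the mature transcript).
gene_exons <- function(models, gene_id) {
  ex <- dplyr::filter(models$features, .data$gene_id == !!gene_id,
                      .data$feature == "exon")
  if (nrow(ex) == 0) stop("gene has no exons: ", gene_id)
  ex <- if (ex$strand[1] == "+") ex[order(ex$start), ] else ex[order(-ex$start), ]
  ex$cum_start <- cumsum(c(0L, head(ex$end - ex$start, -1)))
  ex
}

#' Spliced transcript sequence of a gene
#'
#' Concatenates exon sequences in transcript order; minus-strand genes are
#' reverse-complemented so the result always reads 5' to 3'.
#'
#' @param models Gene models (list of `genes` and `features` tibbles).
#' @param genome Named character vector of chromosome sequences.
#' @param gene_id Gene identifier.
#' @return A single DNA string.
#' @export
transcript_seq <- function(models, genome, gene_id) {
  ex <- gene_exons(models, gene_id)
  paste(vapply(seq_len(nrow(ex)), function(i) {
    genome_seq(genome, ex$chrom[i], ex$start[i], ex$end[i], ex$strand[i])
  }, character(1)), collapse = "")
}

# Map one genomic position (0-based) within an exonic region to its
# transcript coordinate; returns NA when the position is not exonic.
genomic_to_transcript <- function(ex, pos) {
  for (i in seq_len(nrow(ex))) {
    if (pos >= ex$start[i] && pos < ex$end[i]) {
      return(if (ex$strand[i] == "+") ex$cum_start[i] + (pos - ex$start[i])
             else ex$cum_start[i] + (ex$end[i] - 1L - pos))
    }
  }
  NA_integer_
}

#' Transcript-space intervals of an annotated region
#'
#' @param models Gene models.
#' @param gene_id Gene identifier.
#' @param region One of `"three_utr"`, `"five_utr"`, `"cds"`, `"exon"`.
#' @return Tibble with `t_start`, `t_end` (0-based half-open transcript
#'   coordinates), one row per contiguous block.
#' @export
region_transcript_intervals <- function(models, gene_id, region = "three_utr") {
  ex <- gene_exons(models, gene_id)
  fr <- dplyr::filter(models$features, .data$gene_id == !!gene_id,
                      .data$feature == !!region)
  if (nrow(fr) == 0) {
    return(tibble::tibble(t_start = integer(), t_end = integer()))
  }
  out <- lapply(seq_len(nrow(fr)), function(i) {
    # both ends of the block are exonic by the model invariants
    a <- genomic_to_transcript(ex, fr$start[i])
    b <- genomic_to_transcript(ex, fr$end[i] - 1L)
    tibble::tibble(t_start = min(a, b), t_end = max(a, b) + 1L)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$t_start)
}

#' Project a transcript interval onto the genome
#'
#' Sites spanning exon junctions project to multiple genomic intervals.
#'
#' @param models Gene models.
#' @param gene_id Gene identifier.
#' @param t_start,t_end 0-based half-open transcript interval.
#' @return Interval tibble (`chrom`, `start`, `end`, `strand`), one row per
#'   genomic block, ordered along the genome.
#' @export
project_to_genome <- function(models, gene_id, t_start, t_end) {
  ex <- gene_exons(models, gene_id)
  stopifnot(t_start >= 0, t_end > t_start)
  blocks <- list()
  for (i in seq_len(nrow(ex))) {
    elen <- ex$end[i] - ex$start[i]
    lo <- max(t_start, ex$cum_start[i])
    hi <- min(t_end, ex$cum_start[i] + elen)
    if (lo < hi) {
      off_lo <- lo - ex$cum_start[i]
      off_hi <- hi - ex$cum_start[i]
      if (ex$strand[i] == "+") {
        gs <- ex$start[i] + off_lo
        ge <- ex$start[i] + off_hi
      } else {
        gs <- ex$end[i] - off_hi
        ge <- ex$end[i] - off_lo
      }
      blocks[[length(blocks) + 1]] <- tibble::tibble(
        chrom = ex$chrom[i], start = as.integer(gs), end = as.integer(ge),
        strand = ex$strand[i])
    }
  }
  if (length(blocks) == 0) stop("transcript interval outside transcript: ",
                                gene_id, " [", t_start, ",", t_end, ")")
  dplyr::arrange(dplyr::bind_rows(blocks), .data$start)
}
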