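# Internal sequence/interval helpers. All coordinates in this package are
# 0-based half-open on the forward genome strand; sequences are stored in the
# DNA alphabet (U converted to T on ingest).

DNA_CHARS <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `{A,C,G,T}` alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca", intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = FALSE)
}

# U -> T, uppercase; records nothing (callers that need to restore RNA keep
# their own flag).
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Hamming distance between two equal-length strings; Inf if lengths differ.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Random DNA string(s) from the current RNG stream.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_CHARS, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Extract genome substring, 0-based half-open; strand "-" returns the reverse
# complement (the transcribed sequence of a minus-strand feature).
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  s <- substr(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  s
}

# Overwrite genome substring in place (forward-strand sequence), 0-based start.
genome_write <- function(genome, chrom, start, seq) {
  substr(genome[[chrom]], start + 1L, start + nchar(seq)) <- seq
  genome
}

# ranges overlap by >= 1 under half-open semantics
ranges_overlap <- function(s1, e1, s2, e2) {
  pmax(s1, s2) < pmin(e1, e2)
}

new_interval_tbl <- function(chrom = character(), start = integer(),
                             end = integer(), strand = character()) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

assert_intervals <- function(x, what = "interval") {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop(sprintf("invalid %s: start/end inverted or negative at row %d (%s:%d-%d)",
                 what, bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if (!all(x$strand %in% c("+", "-"))) stop(sprintf("invalid %s strand", what))
  invisible(x)
}

# tibble of intervals -> GRanges (1-based closed, as GenomicRanges expects)
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*"
  )
}

# sample-id columns of a wide matrix tibble (everything after the key column)
matrix_samples <- function(x, key = "sequence") {
  setdiff(names(x), key)
}
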