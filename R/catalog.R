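# Unique-read catalog and the filtering cascade: collapse to unique
# sequences, exclude known miRNAs, require within-condition abundance and
# cross-condition recurrence, normalize to reads per million.

#' Collapse per-sample read sets into a unique-sequence count matrix
#'
#' Reads from all samples are pooled, unique sequences become rows, and each
#' cell holds the exact-duplicate count of that sequence in that sample.
#' Total cell sums equal total input reads (conservation).
#'
#' @param read_sets Named list (names = sample ids) of character vectors of
#'   reads (one element per read occurrence).
#' @param samples Sample metadata tibble with at least `sample_id`.
#' @return Wide count tibble: column `sequence` plus one integer column per
#'   sample, rows sorted by sequence.
#' @export
collapse_reads <- function(read_sets, samples) {
  stopifnot(all(names(read_sets) %in% samples$sample_id))
  empty <- names(read_sets)[vapply(read_sets, length, integer(1)) == 0]
  if (length(empty) > 0) {
    warning("empty sample(s): ", paste(empty, collapse = ", "))
  }
  long <- purrr::imap(read_sets, function(reads, sid) {
    if (length(reads) == 0) return(NULL)
    tab <- table(normalize_dna(reads))
    tibble::tibble(sequence = names(tab), sample_id = sid,
                   count = as.integer(tab))
  })
  long <- dplyr::bind_rows(long)
  if (nrow(long) == 0) {
    out <- tibble::tibble(sequence = character())
    for (s in samples$sample_id) out[[s]] <- integer()
    return(out)
  }
  wide <- tidyr::pivot_wider(long, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  for (s in setdiff(samples$sample_id, names(wide))) wide[[s]] <- 0L
  dplyr::arrange(wide[, c("sequence", samples$sample_id)], .data$sequence)
}

#' Align short reads to a genome by Hamming distance
#'
#' Substitution-only matching (no indels) on both strands; minus-strand hits
#' are located by matching the reverse complement against the forward genome.
#' With `report_all = FALSE` only hits in the best (minimum-mismatch) stratum
#' of each sequence are returned; with `report_all = TRUE` every hit with at
#' most `max_mm` substitutions is returned (the all-loci mode used for
#' annotation). Hit order is deterministic: (sequence, chrom, start, strand).
#'
#' @param sequences Character vector of read sequences (>= 15 nt, ACGT only;
#'   offending sequences are dropped and reported in the `rejected`
#'   attribute).
#' @param genome Named character vector of chromosome sequences.
#' @param max_mm Maximum substitutions per hit.
#' @param report_all Report every stratum (`TRUE`) or only the best (`FALSE`).
#' @return Hit tibble: `sequence`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`; attribute `rejected` holds a tibble
#'   of dropped inputs with reason codes.
#' @export
align_short_reads <- function(sequences, genome, max_mm = 2L,
                              report_all = FALSE) {
  sequences <- unique(sequences)
  bad_alpha <- grepl("[^ACGT]", sequences)
  bad_len <- nchar(sequences) < 15
  rejected <- tibble::tibble(
    sequence = sequences[bad_alpha | bad_len],
    reason = ifelse(bad_alpha[bad_alpha | bad_len], "non_acgt", "too_short")
  )
  sequences <- sequences[!(bad_alpha | bad_len)]
  subjects <- lapply(genome, Biostrings::DNAString)
  hits <- purrr::map(sequences, function(s) {
    out <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") s else revcomp(s)
      for (chrom in names(subjects)) {
        m <- Biostrings::matchPattern(pat, subjects[[chrom]],
                                      max.mismatch = max_mm,
                                      with.indels = FALSE)
        if (length(m) == 0) next
        mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat),
                                          subjects[[chrom]],
                                          starting.at = IRanges::start(m))
        out[[length(out) + 1]] <- tibble::tibble(
          sequence = s, chrom = chrom,
          start = IRanges::start(m) - 1L, end = IRanges::end(m),
          strand = strand, mismatches = as.integer(mm))
      }
    }
    if (length(out) == 0) return(NULL)
    tb <- dplyr::bind_rows(out)
    if (!report_all) tb <- tb[tb$mismatches == min(tb$mismatches), ]
    tb
  })
  res <- dplyr::bind_rows(hits)
  if (nrow(res) == 0) {
    res <- tibble::tibble(sequence = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), mismatches = integer())
  }
  res <- dplyr::arrange(res, .data$sequence, .data$chrom, .data$start,
                        .data$strand)
  attr(res, "rejected") <- rejected
  res
}

#' Exclude sequences matching known mature miRNAs
#'
#' A row is removed iff its sequence matches a known mature miRNA within
#' `max_mm` substitutions (default: exact match, equal length).
#'
#' @param counts Wide count tibble from [collapse_reads()].
#' @param known Character vector of known mature miRNA sequences (non-empty).
#' @param max_mm Substitutions tolerated in the match.
#' @return Filtered count tibble; attribute `excluded` holds the removed
#'   sequences.
#' @export
exclude_known_mirnas <- function(counts, known, max_mm = 0L) {
  stopifnot(length(known) > 0)
  known <- normalize_dna(known)
  if (max_mm == 0) {
    drop <- counts$sequence %in% known
  } else {
    drop <- vapply(counts$sequence, function(s) {
      any(vapply(known, function(k) hamming(s, k) <= max_mm, logical(1)))
    }, logical(1))
  }
  out <- counts[!drop, ]
  attr(out, "excluded") <- counts$sequence[drop]
  out
}

#' Apply within-condition abundance and cross-condition recurrence filters
#'
#' A sequence survives iff (a) its summed count within at least one condition
#' reaches `min_reads`, and (b) it has a nonzero count in at least
#' `min_conditions` distinct conditions. Presence in a condition means a
#' summed count of at least one read.
#'
#' @param counts Wide count tibble.
#' @param samples Sample metadata with `sample_id` and `condition_id`.
#' @param min_reads Abundance threshold (summed within a condition).
#' @param min_conditions Recurrence threshold (distinct conditions present).
#' @return Filtered count tibble; attribute `diagnostics` is a per-sequence
#'   tibble recording `max_condition_count`, `n_conditions_present`,
#'   `pass_abundance`, `pass_recurrence`, `kept`.
#' @export
apply_presence_filters <- function(counts, samples, min_reads = 5L,
                                   min_conditions = 2L) {
  conds <- unique(samples$condition_id)
  if (min_conditions > length(conds)) {
    stop("min_conditions (", min_conditions, ") exceeds available conditions (",
         length(conds), ")")
  }
  sample_cols <- matrix_samples(counts)
  if (nrow(counts) == 0) {
    attr(counts, "diagnostics") <- tibble::tibble(
      sequence = character(), max_condition_count = integer(),
      n_conditions_present = integer(), pass_abundance = logical(),
      pass_recurrence = logical(), kept = logical())
    return(counts)
  }
  cond_of <- setNames(samples$condition_id, samples$sample_id)[sample_cols]
  mat <- as.matrix(counts[, sample_cols, drop = FALSE])
  cond_sums <- sapply(conds, function(cc) {
    rowSums(mat[, cond_of == cc, drop = FALSE])
  })
  if (nrow(counts) == 1) cond_sums <- matrix(cond_sums, nrow = 1)
  max_cond <- apply(cond_sums, 1, max)
  n_pres <- rowSums(cond_sums >= 1)
  diag <- tibble::tibble(
    sequence = counts$sequence,
    max_condition_count = as.integer(max_cond),
    n_conditions_present = as.integer(n_pres),
    pass_abundance = max_cond >= min_reads,
    pass_recurrence = n_pres >= min_conditions
  )
  diag$kept <- diag$pass_abundance & diag$pass_recurrence
  out <- counts[diag$kept, ]
  attr(out, "diagnostics") <- diag
  out
}

#' Reads-per-million normalization
#'
#' `RPM[i, s] = count[i, s] * 1e6 / library_size(s)`. Columns with zero
#' library size yield all-zero RPM with a warning.
#'
#' @param counts Wide count tibble.
#' @return Tibble of identical shape holding RPM values.
#' @export
rpm_normalize <- function(counts) {
  out <- counts
  for (s in matrix_samples(counts)) {
    lib <- sum(counts[[s]])
    if (lib == 0) {
      warning("zero library size in sample ", s)
      out[[s]] <- as.double(counts[[s]])
    } else {
      out[[s]] <- counts[[s]] * 1e6 / lib
    }
  }
  out
}
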