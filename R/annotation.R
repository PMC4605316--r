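# Genomic origin classification, annotation summaries, overlap with
# transcriptionally active regions (TAR), and repeat-consensus meta-profiles.
#
# Class priority: exon > ncRNA > repeat > intron > intergenic. Gene-derived
# classes (exon/ncRNA/intron) are sense-matched: the sRNA locus must lie on
# the host gene's strand to count as originating from it -- an antisense
# locus over an exon (e.g. a binding site) is not an exonic origin. Repeat
# and TAR overlaps are strand-agnostic.

CLASS_PRIORITY <- c("exon", "ncRNA", "repeat", "intron", "intergenic")

#' Classify the genomic origin of every sRNA locus
#'
#' Per locus (all-loci alignment mode): `exon` if it overlaps a
#' protein-coding exon on the same strand; else `ncRNA` if it overlaps a
#' non-coding gene's exon on the same strand; else `repeat` if it overlaps a
#' repeat element (any strand); else `intron` if it lies within a same-strand
#' gene body; else `intergenic`. The per-sRNA primary class is the
#' highest-priority class across its loci; the class set retains all.
#'
#' @param hits Alignment hits from [align_short_reads()] with
#'   `report_all = TRUE`.
#' @param models Gene models.
#' @param repeats Repeat element tibble.
#' @return List with `loci` (per-hit tibble incl. `class`, `repeat_family`)
#'   and `calls` (per-sRNA tibble: `sequence`, `primary_class`, `class_set`
#'   list-column, `repeat_family`).
#' @export
classify_loci <- function(hits, models, repeats) {
  if (nrow(hits) == 0) {
    return(list(loci = tibble::tibble(), calls = tibble::tibble(
      sequence = character(), primary_class = character(),
      class_set = list(), repeat_family = character())))
  }
  hg <- as_granges(hits)
  ex <- models$features[models$features$feature == "exon", ]
  coding_ids <- models$genes$gene_id[models$genes$biotype == "protein_coding"]
  ex_cod <- ex[ex$gene_id %in% coding_ids, ]
  ex_nc <- ex[!ex$gene_id %in% coding_ids, ]

  ov_same_strand <- function(iv) {
    if (nrow(iv) == 0) return(rep(FALSE, nrow(hits)))
    g <- as_granges(iv)
    hl <- GenomicRanges::findOverlaps(hg, g, minoverlap = 1L,
                                      ignore.strand = TRUE)
    keep <- hits$strand[S4Vectors::queryHits(hl)] ==
      iv$strand[S4Vectors::subjectHits(hl)]
    seq_len(nrow(hits)) %in% S4Vectors::queryHits(hl)[keep]
  }
  ov_any_strand <- function(iv) {
    if (nrow(iv) == 0) return(rep(FALSE, nrow(hits)))
    hl <- GenomicRanges::findOverlaps(hg, as_granges(iv), minoverlap = 1L,
                                      ignore.strand = TRUE)
    seq_len(nrow(hits)) %in% S4Vectors::queryHits(hl)
  }

  is_exon <- ov_same_strand(ex_cod)
  is_nc <- ov_same_strand(ex_nc)
  is_rep <- ov_any_strand(repeats)
  gene_bodies <- models$genes[, c("chrom", "start", "end", "strand")]
  in_gene <- ov_same_strand(gene_bodies)

  loci <- hits
  loci$class <- ifelse(is_exon, "exon",
                ifelse(is_nc, "ncRNA",
                ifelse(is_rep, "repeat",
                ifelse(in_gene, "intron", "intergenic"))))
  # repeat family of the first overlapping element, for repeat-class loci
  loci$repeat_family <- NA_character_
  if (nrow(repeats) > 0) {
    hl <- GenomicRanges::findOverlaps(hg, as_granges(repeats),
                                      minoverlap = 1L, ignore.strand = TRUE)
    fam <- tapply(repeats$family[S4Vectors::subjectHits(hl)],
                  S4Vectors::queryHits(hl), function(x) x[1])
    loci$repeat_family[as.integer(names(fam))] <- unname(fam)
  }
  loci$repeat_family[loci$class != "repeat"] <- NA_character_

  calls <- loci |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      primary_class = CLASS_PRIORITY[min(match(.data$class, CLASS_PRIORITY))],
      class_set = list(sort(unique(.data$class))),
      repeat_family = if (any(!is.na(.data$repeat_family))) {
        .data$repeat_family[!is.na(.data$repeat_family)][1]
      } else NA_character_,
      .groups = "drop")
  list(loci = loci, calls = calls)
}

#' Summarize annotation classes as counts and percentages
#'
#' Percentage = 100 x count / `total_n`, reported to 2 decimals
#' (round-half-even, R's default rounding). In `all_classes` mode an sRNA
#' contributes to every class in its class set, so counts may sum above
#' `total_n`; `primary` mode counts each sRNA once.
#'
#' @param calls Per-sRNA calls from [classify_loci()], or a named numeric
#'   vector of per-class counts (in which case `total_n` is required).
#' @param total_n Denominator; defaults to the number of sRNAs in `calls`.
#' @param mode `"primary"` or `"all_classes"`.
#' @return Tibble: `class`, `n`, `percentage`.
#' @export
summarize_annotation <- function(calls, total_n = NULL,
                                 mode = c("primary", "all_classes")) {
  mode <- match.arg(mode)
  if (is.numeric(calls) && !is.null(names(calls))) {
    counts <- tibble::tibble(class = names(calls), n = as.numeric(calls))
    if (is.null(total_n)) stop("total_n required with a count vector")
  } else {
    total_n <- total_n %||% nrow(calls)
    counts <- if (mode == "primary") {
      dplyr::count(calls, class = .data$primary_class)
    } else {
      calls |>
        tidyr::unnest_longer("class_set") |>
        dplyr::count(class = .data$class_set)
    }
  }
  stopifnot(total_n >= 1)
  counts$percentage <- round(100 * counts$n / total_n, 2)
  counts <- counts[order(match(counts$class, CLASS_PRIORITY), counts$class), ]
  tibble::as_tibble(counts)
}

#' Overlap sRNA loci with transcriptionally active regions
#'
#' An sRNA is TAR-overlapping iff any of its loci overlaps any TAR interval
#' by one base (strand-agnostic, half-open semantics: abutting intervals do
#' not overlap). When `restrict_to_noncoding` the summary denominator is the
#' sRNAs whose class set excludes `exon`.
#'
#' @param calls Per-sRNA calls from [classify_loci()].
#' @param hits All-loci alignment hits.
#' @param tar TAR interval tibble.
#' @param restrict_to_noncoding Restrict the summary denominator.
#' @return `calls` with a logical `tar` column; attribute `summary` holds
#'   `n_overlapping`, `n_denominator`, `fraction`.
#' @export
tar_overlap <- function(calls, hits, tar, restrict_to_noncoding = TRUE) {
  flag_by_seq <- if (nrow(tar) == 0 || nrow(hits) == 0) {
    setNames(rep(FALSE, nrow(calls)), calls$sequence)
  } else {
    hl <- GenomicRanges::findOverlaps(as_granges(hits), as_granges(tar),
                                      minoverlap = 1L, ignore.strand = TRUE)
    ov_seq <- unique(hits$sequence[S4Vectors::queryHits(hl)])
    setNames(calls$sequence %in% ov_seq, calls$sequence)
  }
  calls$tar <- unname(flag_by_seq[calls$sequence])
  denom <- if (restrict_to_noncoding) {
    !vapply(calls$class_set, function(cs) "exon" %in% cs, logical(1))
  } else rep(TRUE, nrow(calls))
  attr(calls, "summary") <- tibble::tibble(
    n_overlapping = sum(calls$tar & denom),
    n_denominator = sum(denom),
    fraction = if (sum(denom) > 0) sum(calls$tar & denom) / sum(denom) else NA_real_)
  calls
}

#' Repeat-consensus meta-profile of sRNA 5' ends
#'
#' Maps each hit's 5' start onto the family consensus through the copy's
#' recorded `(consensus_offset, orientation)`: for a plus-orientation copy,
#' consensus position = `consensus_offset + pos_in_copy`; for a
#' minus-orientation copy the position is reflected through the copy,
#' `consensus_offset + (copy_length - 1 - pos_in_copy)`. The sRNA's RPM
#' weight is added at that coordinate; positions falling outside the
#' consensus are dropped with a counted warning.
#'
#' @param hits Alignment hits (any mode).
#' @param repeats Repeat element tibble.
#' @param rpm_weights Named numeric vector: sequence -> weight (e.g. group
#'   mean RPM).
#' @param family Repeat family name.
#' @param normalize `"raw"` or `"sum_to_1"`.
#' @return Tibble of class `rsrna_profile`: `family`, `position` (0-based
#'   consensus coordinate), `weight`.
#' @export
consensus_profile <- function(hits, repeats, rpm_weights, family,
                              normalize = c("raw", "sum_to_1")) {
  normalize <- match.arg(normalize)
  fam <- repeats[repeats$family == family, ]
  if (nrow(fam) == 0) stop("unknown repeat family: ", family)
  clen <- fam$consensus_length[1]
  w <- numeric(clen)
  dropped <- 0L
  for (i in seq_len(nrow(hits))) {
    five_prime <- if (hits$strand[i] == "+") hits$start[i] else hits$end[i] - 1L
    cp <- fam[fam$chrom == hits$chrom[i] &
                five_prime >= fam$start & five_prime < fam$end, ]
    if (nrow(cp) == 0) next
    cp <- cp[1, ]
    pos_in_copy <- five_prime - cp$start
    copy_len <- cp$end - cp$start
    cons_pos <- if (cp$strand == "+") {
      cp$consensus_offset + pos_in_copy
    } else {
      cp$consensus_offset + (copy_len - 1L - pos_in_copy)
    }
    if (cons_pos < 0 || cons_pos >= clen) {
      dropped <- dropped + 1L
      next
    }
    w[cons_pos + 1L] <- w[cons_pos + 1L] +
      (rpm_weights[[hits$sequence[i]]] %||% 0)
  }
  if (dropped > 0) {
    warning(dropped, " hit(s) mapped outside the consensus and were dropped")
  }
  if (normalize == "sum_to_1" && sum(w) > 0) w <- w / sum(w)
  out <- tibble::tibble(family = family, position = seq_len(clen) - 1L,
                        weight = w)
  class(out) <- c("rsrna_profile", class(out))
  out
}

#' Per-position group test on consensus profiles
#'
#' Welch t-test per consensus position between two sample groups of
#' sum-to-1-normalized profiles, with Benjamini-Hochberg q-values across
#' positions.
#'
#' @param profiles Tibble: `sample_id`, `position`, `weight` (per-sample
#'   sum-to-1 profiles).
#' @param group_a,group_b Character vectors of sample ids (>= 2 each).
#' @return Tibble per position: `position`, `t`, `p_value`, `q_bh`;
#'   attribute `summary` holds the count and fraction of positions with
#'   p < 0.05.
#' @export
profile_group_test <- function(profiles, group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 samples")
  }
  wide <- tidyr::pivot_wider(profiles, names_from = "sample_id",
                             values_from = "weight", values_fill = 0)
  res <- purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    a <- as.numeric(wide[i, group_a])
    b <- as.numeric(wide[i, group_b])
    tt <- welch_ttest(a, b)
    tibble::tibble(position = wide$position[i], t = tt$t,
                   p_value = tt$p_value)
  })
  res$q_bh <- p.adjust(res$p_value, method = "BH")
  attr(res, "summary") <- tibble::tibble(
    n_significant = sum(res$p_value < 0.05),
    fraction_significant = mean(res$p_value < 0.05))
  res
}
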