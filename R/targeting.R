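# Target prediction and interaction validation. Two independent in-house
# predictors: a seed-match predictor (canonical 8mer/7mer site classes) and
# a duplex predictor (near-full complementarity within a substitution
# budget).
# "Consensus" keeps only (sRNA, gene) pairs where the two predictors report
# overlapping sites. Predicted interactions are then validated against
# Argonaute CLIP peaks/read sets and CLASH chimeric reads, and checked for
# antisense origin.

seed_site_tbl <- function() {
  tibble::tibble(srna_id = character(), sequence = character(),
                 gene_id = character(), region = character(),
                 t_start = integer(), t_end = integer(),
                 seed_class = character(), duplex_mismatches = integer(),
                 seed_predictor = logical(), duplex_predictor = logical(),
                 genomic = list())
}

complementary <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

# region sequence + transcript offset blocks for one gene
region_blocks <- function(models, genome, gene_id, region) {
  iv <- region_transcript_intervals(models, gene_id, region)
  if (nrow(iv) == 0) return(NULL)
  tx <- transcript_seq(models, genome, gene_id)
  list(intervals = iv, tx = tx)
}

#' Predict seed-match target sites
#'
#' Scans the requested transcript regions (default 3' UTR) of every gene for
#' exact matches to the reverse complement of sRNA positions 2-8 (1-based
#' from the 5' end). Site classes follow the canonical taxonomy: `8mer`
#' (positions 2-8 matched plus target A opposite position 1), `7mer-m8`
#' (positions 2-8 matched, no A anchor), `7mer-A1` (positions 2-7 matched
#' plus A anchor, position 8 unmatched).
#'
#' @param srnas Tibble with `srna_id` and `sequence` (each >= 15 nt), or a
#'   character vector of sequences.
#' @param models Gene models.
#' @param genome Named character vector of chromosome sequences.
#' @param regions Regions to scan (`"three_utr"`, `"five_utr"`, `"cds"`).
#' @return Site tibble with transcript coordinates (`t_start`, `t_end`,
#'   0-based half-open), `seed_class`, predictor flags, and a `genomic`
#'   list-column of projected genomic interval tibbles.
#' @export
predict_seed_sites <- function(srnas, models, genome, regions = "three_utr") {
  srnas <- as_srna_tbl(srnas)
  if (any(nchar(srnas$sequence) < 8)) stop("sRNA shorter than 8 nt")
  seed7_rcs <- revcomp(substr(srnas$sequence, 2, 8))  # target-sense 7mers
  seed6_rcs <- revcomp(substr(srnas$sequence, 2, 7))  # target-sense 6mers
  out <- list()
  for (gid in models$genes$gene_id) {
    for (region in regions) {
      rb <- region_blocks(models, genome, gid, region)
      if (is.null(rb)) next
      for (k in seq_len(nrow(srnas))) {
        s <- srnas$sequence[k]
        seed7_rc <- seed7_rcs[k]
        seed6_rc <- seed6_rcs[k]
        for (b in seq_len(nrow(rb$intervals))) {
          t0 <- rb$intervals$t_start[b]; t1 <- rb$intervals$t_end[b]
          block <- substr(rb$tx, t0 + 1, t1)
          hits7 <- gregexpr(seed7_rc, block, fixed = TRUE)[[1]]
          hits7 <- hits7[hits7 > 0]
          for (h in hits7) {
            t <- t0 + h - 1L                   # 0-based start of 7mer on transcript
            a_pos <- t + 7L                    # base opposite srna position 1
            a_anchor <- a_pos < nchar(rb$tx) &&
              substr(rb$tx, a_pos + 1, a_pos + 1) == "A"
            cls <- if (a_anchor) "8mer" else "7mer-m8"
            t_end <- if (a_anchor) t + 8L else t + 7L
            out[[length(out) + 1]] <- tibble::tibble(
              srna_id = srnas$srna_id[k], sequence = s, gene_id = gid,
              region = region, t_start = t, t_end = t_end, seed_class = cls)
          }
          # 7mer-A1: 6mer match + A anchor, with position 8 NOT matched
          hits6 <- gregexpr(seed6_rc, block, fixed = TRUE)[[1]]
          hits6 <- hits6[hits6 > 0]
          for (h in hits6) {
            t <- t0 + h - 1L
            a_pos <- t + 6L
            if (!(a_pos < nchar(rb$tx) &&
                  substr(rb$tx, a_pos + 1, a_pos + 1) == "A")) next
            p8_pos <- t - 1L                   # target base pairing srna position 8
            p8_match <- p8_pos >= 0 &&
              complementary(substr(rb$tx, p8_pos + 1, p8_pos + 1),
                            substr(s, 8, 8))
            if (p8_match) next                 # already reported as 8mer
            out[[length(out) + 1]] <- tibble::tibble(
              srna_id = srnas$srna_id[k], sequence = s, gene_id = gid,
              region = region, t_start = t, t_end = t + 7L,
              seed_class = "7mer-A1")
          }
        }
      }
    }
  }
  finalize_sites(out, models, seed = TRUE)
}

#' Predict duplex target sites
#'
#' Slides a window of the sRNA's length across the requested transcript
#' regions and reports every window whose reverse complement is within
#' `max_mm` substitutions of the sRNA (G:U wobble counted as mismatch).
#'
#' @inheritParams predict_seed_sites
#' @param max_mm Maximum substitutions in the duplex.
#' @return Site tibble as in [predict_seed_sites()], with
#'   `duplex_mismatches` filled in.
#' @export
predict_duplex_sites <- function(srnas, models, genome, max_mm = 2L,
                                 regions = "three_utr") {
  srnas <- as_srna_tbl(srnas)
  targets <- revcomp(srnas$sequence)           # perfect-complement windows
  out <- list()
  for (gid in models$genes$gene_id) {
    for (region in regions) {
      rb <- region_blocks(models, genome, gid, region)
      if (is.null(rb)) next
      for (k in seq_len(nrow(srnas))) {
        s <- srnas$sequence[k]
        target <- targets[k]
        for (b in seq_len(nrow(rb$intervals))) {
          t0 <- rb$intervals$t_start[b]; t1 <- rb$intervals$t_end[b]
          if (t1 - t0 < nchar(s)) next
          block <- Biostrings::DNAString(substr(rb$tx, t0 + 1, t1))
          m <- Biostrings::matchPattern(target, block, max.mismatch = max_mm,
                                        with.indels = FALSE)
          if (length(m) == 0) next
          mm <- Biostrings::neditStartingAt(Biostrings::DNAString(target),
                                            block,
                                            starting.at = IRanges::start(m))
          for (j in seq_along(m)) {
            t <- t0 + IRanges::start(m)[j] - 1L
            out[[length(out) + 1]] <- tibble::tibble(
              srna_id = srnas$srna_id[k], sequence = s, gene_id = gid,
              region = region, t_start = t, t_end = t + nchar(s),
              duplex_mismatches = as.integer(mm[j]))
          }
        }
      }
    }
  }
  finalize_sites(out, models, seed = FALSE)
}

as_srna_tbl <- function(srnas) {
  if (is.character(srnas)) {
    srnas <- tibble::tibble(
      srna_id = paste0("srna_", seq_along(srnas)), sequence = srnas)
  }
  srnas$sequence <- normalize_dna(srnas$sequence)
  srnas
}

finalize_sites <- function(rows, models, seed) {
  if (length(rows) == 0) return(seed_site_tbl())
  tb <- dplyr::bind_rows(rows)
  if (!"seed_class" %in% names(tb)) tb$seed_class <- "none"
  if (!"duplex_mismatches" %in% names(tb)) tb$duplex_mismatches <- NA_integer_
  tb$seed_predictor <- seed
  tb$duplex_predictor <- !seed
  tb$genomic <- purrr::map2(tb$gene_id, seq_len(nrow(tb)), function(g, i) {
    project_to_genome(models, g, tb$t_start[i], tb$t_end[i])
  })
  dplyr::arrange(tb, .data$srna_id, .data$gene_id, .data$t_start)
}

#' Consensus of seed and duplex predictions
#'
#' Keeps (sRNA, gene) pairs where a seed site and a duplex site overlap by at
#' least one transcript position; the merged site carries both predictor
#' flags, the union interval, the seed class and the duplex mismatch count.
#'
#' @param seed_sites,duplex_sites Site tibbles from the two predictors.
#' @param models Gene models (for re-projecting the union interval).
#' @return Consensus site tibble.
#' @export
consensus_sites <- function(seed_sites, duplex_sites, models) {
  if (nrow(seed_sites) == 0 || nrow(duplex_sites) == 0) return(seed_site_tbl())
  joined <- dplyr::inner_join(
    dplyr::select(seed_sites, "srna_id", "sequence", "gene_id", "region",
                  ss = "t_start", se = "t_end", "seed_class"),
    dplyr::select(duplex_sites, "srna_id", "gene_id", "region",
                  ds = "t_start", de = "t_end", "duplex_mismatches"),
    by = c("srna_id", "gene_id", "region"),
    relationship = "many-to-many")
  joined <- dplyr::filter(joined, ranges_overlap(.data$ss, .data$se,
                                                 .data$ds, .data$de))
  if (nrow(joined) == 0) return(seed_site_tbl())
  merged <- joined |>
    dplyr::mutate(t_start = pmin(.data$ss, .data$ds),
                  t_end = pmax(.data$se, .data$de)) |>
    dplyr::group_by(.data$srna_id, .data$sequence, .data$gene_id,
                    .data$region, .data$t_start, .data$t_end) |>
    dplyr::summarise(
      seed_class = .data$seed_class[which.max(match(
        .data$seed_class, c("8mer", "7mer-m8", "7mer-A1")) * -1)],
      duplex_mismatches = min(.data$duplex_mismatches), .groups = "drop")
  merged$seed_predictor <- TRUE
  merged$duplex_predictor <- TRUE
  merged$genomic <- purrr::map(seq_len(nrow(merged)), function(i) {
    project_to_genome(models, merged$gene_id[i], merged$t_start[i],
                      merged$t_end[i])
  })
  dplyr::arrange(merged, .data$srna_id, .data$gene_id, .data$t_start)
}

site_overlaps_intervals <- function(genomic, iv, slop = 0L) {
  if (nrow(iv) == 0) return(FALSE)
  any(vapply(seq_len(nrow(genomic)), function(i) {
    any(genomic$chrom[i] == iv$chrom &
          ranges_overlap(genomic$start[i] - slop, genomic$end[i] + slop,
                         iv$start, iv$end))
  }, logical(1)))
}

#' Flag sites supported by Argonaute CLIP evidence
#'
#' A site gains the flag for Argonaute protein K iff its genomic projection
#' overlaps at least one AGO-K peak by one base AND the sRNA sequence is
#' present (exact match) in the AGO-K read set. Flags are independent across
#' proteins.
#'
#' @param sites Site tibble.
#' @param ago_peaks Named list (`ago1`..`ago4`) of peak interval tibbles.
#' @param ago_reads Named list (same names) of character vectors of CLIP
#'   reads.
#' @param mode `"conjunction"` (default) requires peak overlap and read-set
#'   presence; `"disjunction"` accepts either.
#' @return `sites` with one logical column per Argonaute.
#' @export
clip_support <- function(sites, ago_peaks, ago_reads,
                         mode = c("conjunction", "disjunction")) {
  mode <- match.arg(mode)
  valid <- paste0("ago", 1:4)
  if (!all(names(ago_peaks) %in% valid) || !all(names(ago_reads) %in% valid)) {
    stop("unknown AGO label; expected ago1..ago4")
  }
  for (ak in names(ago_peaks)) {
    reads <- unique(normalize_dna(ago_reads[[ak]] %||% character()))
    sites[[ak]] <- vapply(seq_len(nrow(sites)), function(i) {
      peak_ok <- site_overlaps_intervals(sites$genomic[[i]], ago_peaks[[ak]])
      read_ok <- sites$sequence[i] %in% reads
      if (mode == "conjunction") peak_ok && read_ok else peak_ok || read_ok
    }, logical(1))
  }
  for (ak in setdiff(valid, names(ago_peaks))) sites[[ak]] <- FALSE
  sites
}

#' Flag sites supported by CLASH chimeric reads
#'
#' A site gains the `clash` flag iff some chimera's sRNA segment is within
#' `srna_max_mm` substitutions of the sRNA and the chimera's target fragment
#' overlaps the site's genomic projection expanded by `slop_nt` on each side.
#'
#' @param sites Site tibble.
#' @param chimeras Tibble with `read_id`, `srna_seq`, `chrom`, `start`,
#'   `end`, `strand`.
#' @param slop_nt Expansion of the site projection on each side.
#' @param srna_max_mm Substitutions tolerated between chimera sRNA segment
#'   and the site's sRNA.
#' @return `sites` with a logical `clash` column.
#' @export
clash_support <- function(sites, chimeras, slop_nt = 25L, srna_max_mm = 1L) {
  sites$clash <- vapply(seq_len(nrow(sites)), function(i) {
    if (nrow(chimeras) == 0) return(FALSE)
    seq_ok <- vapply(chimeras$srna_seq, function(cs) {
      hamming(normalize_dna(cs), sites$sequence[i]) <= srna_max_mm
    }, logical(1))
    if (!any(seq_ok)) return(FALSE)
    site_overlaps_intervals(sites$genomic[[i]],
                            chimeras[seq_ok, c("chrom", "start", "end")],
                            slop = slop_nt)
  }, logical(1))
  sites
}

#' Flag sites of antisense origin
#'
#' A site is antisense-origin iff some genomic alignment hit of its sRNA
#' overlaps the site's genomic projection by one base and lies on the strand
#' opposite the target gene.
#'
#' @param sites Site tibble.
#' @param hits Alignment hit tibble from [align_short_reads()].
#' @param models Gene models (for gene strands).
#' @return `sites` with a logical `antisense` column.
#' @export
detect_antisense_origin <- function(sites, hits, models) {
  strand_of <- setNames(models$genes$strand, models$genes$gene_id)
  sites$antisense <- vapply(seq_len(nrow(sites)), function(i) {
    h <- hits[hits$sequence == sites$sequence[i], ]
    if (nrow(h) == 0) return(FALSE)
    h <- h[h$strand != strand_of[[sites$gene_id[i]]], ]
    if (nrow(h) == 0) return(FALSE)
    site_overlaps_intervals(sites$genomic[[i]], h[, c("chrom", "start", "end")])
  }, logical(1))
  sites
}
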