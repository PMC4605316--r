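# Biogenesis-dependence classification and hairpin/Microprocessor motif
# analysis. Dependence on a processing factor is read off knockdown
# exclusivity: present in wild type (and CLIP, when available), totally
# absent upon knockdown. Hairpin detection is a purpose-built single-stem
# maximizer: over all choices of arms and loop it maximizes the number of
# nested Watson-Crick/G:U pairs, with bulges free and no multiloops --
# deterministic and exactly testable against exhaustive enumeration, unlike
# free-energy folding.

#' Count reads matching an sRNA in a read set
#'
#' @param srna sRNA sequence.
#' @param read_set Character vector of reads (one element per occurrence).
#' @param max_mm Substitutions tolerated (default exact).
#' @return Integer count.
#' @export
readset_presence <- function(srna, read_set, max_mm = 0L) {
  srna <- normalize_dna(srna)
  if (length(read_set) == 0) return(0L)
  read_set <- normalize_dna(read_set)
  if (max_mm == 0) return(sum(read_set == srna))
  sum(vapply(read_set, function(r) hamming(r, srna) <= max_mm, logical(1)))
}

#' Call dependence on a processing factor from WT/KD/CLIP read sets
#'
#' `dependent` iff the wild-type count reaches `min_wt`, the knockdown count
#' is exactly zero ("totally absent"), and -- when a CLIP set is supplied --
#' the sRNA appears in it at least once. `independent` iff the knockdown
#' count itself reaches `min_wt`. Anything else is `indeterminate`.
#'
#' @param srna sRNA sequence.
#' @param wt_set,kd_set Wild-type and knockdown read sets.
#' @param clip_set Optional CLIP read set (`NULL` to skip the CLIP clause).
#' @param min_wt Minimum wild-type evidence (default 5, the abundance
#'   threshold).
#' @param kd_max Maximum knockdown count still treated as absent (default 0;
#'   configurable for noisy data).
#' @return One of `"dependent"`, `"independent"`, `"indeterminate"`.
#' @export
dependence_call <- function(srna, wt_set, kd_set, clip_set = NULL,
                            min_wt = 5L, kd_max = 0L) {
  stopifnot(min_wt >= 1)
  wt <- readset_presence(srna, wt_set)
  kd <- readset_presence(srna, kd_set)
  clip_ok <- is.null(clip_set) || readset_presence(srna, clip_set) >= 1
  if (wt >= min_wt && kd <= kd_max && clip_ok) return("dependent")
  if (kd >= min_wt) return("independent")
  "indeterminate"
}

# TRUE where characters a, b can pair (Watson-Crick or G:U on DNA alphabet).
can_pair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

#' Detect the maximal single hairpin in a sequence window
#'
#' Finds the single-stem structure (nested pairs along one stem, bulges
#' allowed as unpaired positions, no multiloops) maximizing the number of
#' paired bases, over all choices of precursor and loop. Pairs may be
#' Watson-Crick or G:U; the loop must be at least `min_loop_nt` long. Ties
#' are broken toward the shorter precursor, then the leftmost one. Runs an
#' O(n^2) two-arm dynamic program (prefix vs suffix maximal nested matching).
#'
#' @param window_seq Window sequence (DNA alphabet; U accepted).
#' @param min_stem_pairs Minimum paired bases for a reported hairpin.
#' @param min_loop_nt Minimum loop length.
#' @return `NULL` if no structure reaches `min_stem_pairs`; otherwise a list
#'   of class `rsrna_hairpin` with 0-based half-open window coordinates:
#'   `precursor`, `arm5`, `arm3`, `loop` (each `c(start, end)`), `n_pairs`,
#'   and `pairs` (tibble of 0-based paired positions `p`, `q`).
#' @export
detect_hairpin <- function(window_seq, min_stem_pairs = 16L, min_loop_nt = 3L) {
  min_stem_pairs <- as.integer(min_stem_pairs)
  min_loop_nt <- as.integer(min_loop_nt)
  s <- strsplit(normalize_dna(window_seq), "")[[1]]
  n <- length(s)
  if (n < 2 * min_stem_pairs + min_loop_nt) {
    stop("window too short for requested stem/loop: ", n, " nt")
  }
  # D[a+1, b] = max nested pairs between prefix s[1..a] and suffix s[b..n];
  # row recurrence collapses to a reverse cummax (see below).
  D <- matrix(0L, nrow = n + 1, ncol = n + 2)  # a in 0..n; b in 1..n+1
  for (a in seq_len(n)) {
    prev <- D[a, ]                             # row a-1
    tmp <- prev[1:(n + 1)]
    pairable <- can_pair(s[a], s)              # s[a] vs s[b], b = 1..n
    tmp[1:n] <- pmax(tmp[1:n], prev[2:(n + 1)] + as.integer(pairable))
    D[a + 1, 1:(n + 1)] <- rev(cummax(rev(tmp)))
  }
  # valid anchors: loop window [a+1, a+min_loop] unpaired => b0 = a+min_loop+1
  amax <- n - min_loop_nt
  scores <- vapply(0:amax, function(a) D[a + 1, a + min_loop_nt + 1],
                   integer(1))
  best <- max(scores)
  if (best < min_stem_pairs) return(NULL)
  cand <- (0:amax)[scores == best]
  structs <- lapply(cand, function(a) {
    traceback_hairpin(D, s, a, a + min_loop_nt + 1L, n)
  })
  span <- vapply(structs, function(x) x$precursor[2] - x$precursor[1], integer(1))
  lft <- vapply(structs, function(x) x$precursor[1], integer(1))
  pick <- order(span, lft)[1]
  st <- structs[[pick]]
  st$n_pairs <- best
  class(st) <- "rsrna_hairpin"
  st
}

# Traceback from anchor (a, b), preferring pair moves over skips so pairs sit
# as close to the loop as possible, which makes the outermost pair -- and
# hence the precursor -- as short as the optimum allows. Pairs are recorded
# innermost first (a decreases, b increases as we walk outward).
traceback_hairpin <- function(D, s, a, b, n) {
  ps <- integer(0); qs <- integer(0)
  while (a >= 1 && b <= n) {
    here <- D[a + 1, b]
    if (here == 0L) break
    if (can_pair(s[a], s[b]) && here == D[a, b + 1] + 1L) {
      ps <- c(ps, a); qs <- c(qs, b)
      a <- a - 1L; b <- b + 1L
    } else if (here == D[a, b]) {
      a <- a - 1L
    } else {
      b <- b + 1L
    }
  }
  inner_p <- ps[1]; inner_q <- qs[1]
  outer_p <- ps[length(ps)]; outer_q <- qs[length(qs)]
  list(
    precursor = c(outer_p - 1L, outer_q),
    arm5 = c(outer_p - 1L, inner_p),
    loop = c(inner_p, inner_q - 1L),
    arm3 = c(inner_q - 1L, outer_q),
    pairs = tibble::tibble(p = rev(ps) - 1L, q = rev(qs) - 1L)
  )
}

#' Is an sRNA placed within a hairpin arm?
#'
#' `TRUE` iff all but at most `tolerance_nt` positions of the sRNA interval
#' lie within a single arm of the hairpin.
#'
#' @param hairpin Result of [detect_hairpin()].
#' @param srna_interval 0-based half-open `c(start, end)` of the sRNA within
#'   the same window.
#' @param tolerance_nt Bases allowed to protrude beyond the arm.
#' @return Logical flag.
#' @export
locate_in_stem <- function(hairpin, srna_interval, tolerance_nt = 2L) {
  stopifnot(inherits(hairpin, "rsrna_hairpin"), length(srna_interval) == 2)
  s <- srna_interval[1]; e <- srna_interval[2]
  if (s < 0 || e <= s) stop("invalid sRNA interval")
  len <- e - s
  inside <- function(arm) {
    max(0, min(e, arm[2]) - max(s, arm[1]))
  }
  max(inside(hairpin$arm5), inside(hairpin$arm3)) >= len - tolerance_nt
}

#' Scan Drosha-processing motifs around a precursor
#'
#' Three positional signatures of efficient Microprocessor processing:
#' a CNNC tetramer starting near 17 nt downstream of the precursor 3' end
#' (offset 1 = first downstream base), basal U/G at offsets -14/-13 upstream
#' of the precursor 5' end (offset -1 = immediately preceding base), and a
#' UGU/GUG within the apical loop.
#'
#' @param window_seq Window sequence.
#' @param precursor 0-based half-open `c(start, end)` of the precursor in the
#'   window.
#' @param loop 0-based half-open `c(start, end)` of the loop.
#' @param config [pipeline_config()] (positions and tolerances).
#' @return Tibble with logical (or `NA` when the flank is insufficient)
#'   `cnnc`, `basal_u`, `basal_g`, `basal_ug`, `apical_ugu`,
#'   `all_three_motifs`.
#' @export
scan_processing_motifs <- function(window_seq, precursor, loop,
                                   config = pipeline_config()) {
  s <- normalize_dna(window_seq)
  n <- nchar(s)
  ps <- precursor[1]; pe <- precursor[2]
  stopifnot(ps >= 0, pe > ps, pe <= n, loop[1] >= ps, loop[2] <= pe)
  ch <- function(i) substr(s, i + 1, i + 1)  # 0-based accessor

  need_down <- config$cnnc_center + config$cnnc_tolerance + 3L
  if (n - pe < need_down) {
    warning("insufficient downstream flank for CNNC scan")
    cnnc <- NA
  } else {
    offs <- (config$cnnc_center - config$cnnc_tolerance):
      (config$cnnc_center + config$cnnc_tolerance)
    cnnc <- any(vapply(offs, function(off) {
      p <- pe + off - 1L                      # 0-based start of tetramer
      ch(p) == "C" && ch(p + 3L) == "C"
    }, logical(1)))
  }

  need_up <- -config$basal_u_pos
  if (ps < need_up) {
    warning("insufficient upstream flank for basal UG scan")
    basal_u <- NA; basal_g <- NA
  } else {
    basal_u <- ch(ps + config$basal_u_pos) == "T"
    basal_g <- ch(ps + config$basal_g_pos) == "G"
  }
  basal_ug <- basal_u & basal_g

  loop_seq <- substr(s, loop[1] + 1, loop[2])
  apical_ugu <- grepl("TGT", loop_seq, fixed = TRUE) ||
    grepl("GTG", loop_seq, fixed = TRUE)

  tibble::tibble(cnnc = cnnc, basal_u = basal_u, basal_g = basal_g,
                 basal_ug = basal_ug, apical_ugu = apical_ugu,
                 all_three_motifs = cnnc & basal_ug & apical_ugu)
}

#' Full biogenesis profile for a set of sRNA candidates
#'
#' For each sRNA: dependence calls for Dicer, DGCR8 and Drosha from the
#' perturbation read sets, TRBP CLIP presence, hairpin analysis on the
#' genomic window (sRNA locus of the best alignment hit extended by
#' `config$flank_bp` on each side), stem placement, and processing motifs at
#' the detected precursor.
#'
#' @param srnas Tibble with `srna_id`, `sequence`.
#' @param hits Alignment hits (best stratum) for the sequences.
#' @param genome Named character vector of chromosome sequences.
#' @param perturbations Named list of read sets: `wt`, `dicer_kd`,
#'   `dgcr8_kd`, `drosha_kd`, `dicer_clip`, `trbp_clip`, `dgcr8_clip`.
#' @param config [pipeline_config()].
#' @return One row per sRNA: dependence calls, `trbp_clip` count,
#'   `hairpin_found`, `n_stem_pairs`, `in_stem`, motif flags.
#' @export
biogenesis_profile <- function(srnas, hits, genome, perturbations,
                               config = pipeline_config()) {
  p <- perturbations
  purrr::map_dfr(seq_len(nrow(srnas)), function(k) {
    s <- srnas$sequence[k]
    dicer <- dependence_call(s, p$wt, p$dicer_kd, p$dicer_clip,
                             min_wt = config$min_reads)
    dgcr8 <- dependence_call(s, p$wt, p$dgcr8_kd, p$dgcr8_clip,
                             min_wt = config$min_reads)
    drosha <- dependence_call(s, p$wt, p$drosha_kd, NULL,
                              min_wt = config$min_reads)
    trbp <- readset_presence(s, p$trbp_clip %||% character())

    h <- hits[hits$sequence == s, ]
    hairpin_found <- FALSE; in_stem <- NA; n_stem_pairs <- 0L
    motifs <- tibble::tibble(cnnc = NA, basal_u = NA, basal_g = NA,
                             basal_ug = NA, apical_ugu = NA,
                             all_three_motifs = NA)
    if (nrow(h) > 0) {
      h <- h[order(h$mismatches, h$chrom, h$start), ][1, ]
      w0 <- max(0L, h$start - config$flank_bp)
      w1 <- min(nchar(genome[[h$chrom]]), h$end + config$flank_bp)
      win <- genome_seq(genome, h$chrom, w0, w1, h$strand)
      if (w1 - w0 >= 2 * config$min_stem_pairs + config$min_loop_nt) {
        hp <- detect_hairpin(win, config$min_stem_pairs, config$min_loop_nt)
        if (!is.null(hp)) {
          hairpin_found <- TRUE
          n_stem_pairs <- hp$n_pairs
          # sRNA interval in window coordinates follows the window's strand
          iv <- if (h$strand == "+") c(h$start - w0, h$end - w0)
                else c(w1 - h$end, w1 - h$start)
          in_stem <- locate_in_stem(hp, iv, config$stem_tolerance_nt)
          motifs <- suppressWarnings(
            scan_processing_motifs(win, hp$precursor, hp$loop, config))
        }
      }
    }
    tibble::tibble(
      srna_id = srnas$srna_id[k], sequence = s,
      dicer_call = dicer, dgcr8_call = dgcr8, drosha_call = drosha,
      trbp_clip_count = trbp,
      hairpin_found = hairpin_found, n_stem_pairs = n_stem_pairs,
      in_stem = in_stem) |>
      dplyr::bind_cols(motifs)
  })
}
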