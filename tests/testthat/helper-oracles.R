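# Independent brute-force oracles. These deliberately avoid the code paths
# (Biostrings matching, the two-arm DP) used by the implementation.

# reverse complement by lookup, independent of rsrnakit::revcomp
oracle_rc <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# all Hamming hits of `read` in `genome` (named character vector), both
# strands, via an explicit all-positions character scan
oracle_align <- function(read, genome, max_mm) {
  res <- list()
  L <- nchar(read)
  for (chrom in names(genome)) {
    gch <- strsplit(genome[[chrom]], "")[[1]]
    n <- length(gch)
    if (n < L) next
    for (strand in c("+", "-")) {
      pch <- strsplit(if (strand == "+") read else oracle_rc(read), "")[[1]]
      # position-by-position mismatch counts over all offsets
      win <- sapply(seq_len(L), function(k) gch[k:(n - L + k)])
      if (n - L + 1 == 1) win <- matrix(win, nrow = 1)
      mm <- rowSums(t(t(win) != pch))
      keep <- which(mm <= max_mm)
      if (length(keep) > 0) {
        res[[length(res) + 1]] <- data.frame(
          sequence = read, chrom = chrom, start = keep - 1L,
          end = keep - 1L + L, strand = strand,
          mismatches = as.integer(mm[keep]))
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(sequence = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  }
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start, out$strand), ]
}

# all duplex windows: positions in `utr_seq` whose reverse complement is
# within max_mm substitutions of `srna`
oracle_duplex <- function(srna, utr_seq, max_mm) {
  L <- nchar(srna)
  target <- oracle_rc(srna)
  tch <- strsplit(target, "")[[1]]
  uch <- strsplit(utr_seq, "")[[1]]
  n <- length(uch)
  if (n < L) return(data.frame(t_start = integer(), mismatches = integer()))
  rows <- lapply(0:(n - L), function(t0) {
    mm <- sum(uch[(t0 + 1):(t0 + L)] != tch)
    if (mm <= max_mm) data.frame(t_start = t0, mismatches = mm) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(t_start = integer(), mismatches = integer())
  else out
}

# maximum paired bases of a single nested stem (no bifurcation) with
# Watson-Crick or G:U pairs and loop >= min_loop: Nussinov-style recursion,
# an independent route to the same optimum as the two-arm DP
oracle_hairpin_score <- function(seq, min_loop) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  pairable <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  H <- matrix(0L, n, n)
  for (span in 2:n) {
    for (i in seq_len(n - span + 1)) {
      j <- i + span - 1
      best <- max(H[i + 1, j], H[i, j - 1])
      if (j - i - 1 >= min_loop && pairable(s[i], s[j])) {
        inner <- if (j - i >= 2) H[i + 1, j - 1] else 0L
        best <- max(best, inner + 1L)
      }
      H[i, j] <- best
    }
  }
  H[1, n]
}

# structural validity of a detect_hairpin() result on its window
check_hairpin_structure <- function(hp, window_seq, min_loop) {
  s <- strsplit(toupper(window_seq), "")[[1]]
  p <- hp$pairs$p + 1; q <- hp$pairs$q + 1
  ok_pairs <- all(paste0(s[p], s[q]) %in%
                    c("AT", "TA", "CG", "GC", "GT", "TG"))
  nested <- all(diff(p) > 0) && all(diff(q) < 0)
  loop_ok <- (min(q) - max(p) - 1) >= min_loop
  ok_pairs && nested && loop_ok && nrow(hp$pairs) == hp$n_pairs
}

# exact hypergeometric upper tail by log-binomial summation (no phyper)
oracle_hyper_upper <- function(k, K, N, n) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  if (length(js) == 0) return(0)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# textbook Welch t-test
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
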