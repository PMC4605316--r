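srna_tbl <- function(seqs) {
  tibble::tibble(srna_id = sprintf("r%02d", seq_along(seqs)), sequence = seqs)
}

test_that("seed sites are found at constructed complements with correct classes", {
  srna <- "TGAGGTAGTAGGTTGTATAGTT"  # 22 nt
  seed7_rc <- oracle_rc(substr(srna, 2, 8))
  # 8mer: 7mer site followed by A (opposite position 1)
  utr <- paste0(strrep("C", 30), seed7_rc, "A", strrep("C", 30))
  tg <- toy_gene(utr)
  sites <- predict_seed_sites(srna_tbl(srna), tg$models, tg$genome)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$seed_class, "8mer")
  # 7mer-m8: no A anchor
  utr2 <- paste0(strrep("C", 30), seed7_rc, "G", strrep("C", 30))
  tg2 <- toy_gene(utr2)
  s2 <- predict_seed_sites(srna_tbl(srna), tg2$models, tg2$genome)
  expect_equal(s2$seed_class, "7mer-m8")
  # 7mer-A1: 6mer + A anchor, position 8 mismatched
  seed6_rc <- oracle_rc(substr(srna, 2, 7))
  p8 <- substr(srna, 8, 8)
  not_comp8 <- setdiff(c("A", "C", "G", "T"), oracle_rc(p8))[1]
  utr3 <- paste0(strrep("C", 30), not_comp8, seed6_rc, "A", strrep("C", 30))
  tg3 <- toy_gene(utr3)
  s3 <- predict_seed_sites(srna_tbl(srna), tg3$models, tg3$genome)
  expect_true("7mer-A1" %in% s3$seed_class)
  # a UTR lacking the 7mer (and 6mer+A) yields nothing
  tg4 <- toy_gene(strrep("C", 80))
  expect_equal(nrow(predict_seed_sites(srna_tbl(srna), tg4$models, tg4$genome)), 0)
  expect_error(predict_seed_sites(srna_tbl("ACGT"), tg4$models, tg4$genome),
               "shorter")
})

test_that("duplex sites equal the exhaustive sliding-window oracle", {
  set.seed(31)
  for (rep in 1:25) {
    srna <- random_dna_str(sample(17:24, 1))
    utr <- random_dna_str(120)
    if (rep <= 8) {
      # plant a near-complement to guarantee non-trivial cases
      site <- oracle_rc(srna)
      nmut <- rep %% 4
      if (nmut > 0) {
        at <- sample(nchar(site), nmut)
        sch <- strsplit(site, "")[[1]]
        sch[at] <- vapply(sch[at], function(ch) {
          sample(setdiff(c("A", "C", "G", "T"), ch), 1)
        }, character(1))
        site <- paste(sch, collapse = "")
      }
      pos <- sample(120 - nchar(site), 1)
      substr(utr, pos, pos + nchar(site) - 1) <- site
    }
    tg <- toy_gene(utr)
    got <- predict_duplex_sites(srna_tbl(srna), tg$models, tg$genome, max_mm = 2)
    want <- oracle_duplex(srna, utr, 2)
    utr_t0 <- 200 - 120  # UTR occupies the transcript tail
    expect_equal(sort(got$t_start - utr_t0), sort(want$t_start))
    expect_equal(got$duplex_mismatches[order(got$t_start)],
                 want$mismatches[order(want$t_start)])
  }
})

test_that("raising the duplex mismatch budget never removes sites", {
  set.seed(32)
  srna <- random_dna_str(20)
  utr <- random_dna_str(100)
  site <- oracle_rc(srna); substr(site, 4, 4) <- "A"; substr(site, 9, 9) <- "A"
  substr(utr, 30, 49) <- site
  tg <- toy_gene(utr)
  for (mm in 0:2) {
    lo <- predict_duplex_sites(srna_tbl(srna), tg$models, tg$genome, max_mm = mm)
    hi <- predict_duplex_sites(srna_tbl(srna), tg$models, tg$genome, max_mm = mm + 1)
    expect_true(all(lo$t_start %in% hi$t_start))
  }
})

test_that("consensus keeps exactly the dual-predictor pairs", {
  srna_a <- "TGAGGTAGTAGGTTGTATAGTT"   # gets a full-complement site (both)
  srna_b <- "CCTTGGAACCTTGGAACCTT"     # gets only a seed site
  utr <- paste0(strrep("A", 10), oracle_rc(srna_a), strrep("A", 10),
                oracle_rc(substr(srna_b, 2, 8)), "G", strrep("A", 10))
  tg <- toy_gene(utr)
  srnas <- srna_tbl(c(srna_a, srna_b))
  seed <- predict_seed_sites(srnas, tg$models, tg$genome)
  dup <- predict_duplex_sites(srnas, tg$models, tg$genome)
  cons <- consensus_sites(seed, dup, tg$models)
  expect_setequal(unique(cons$sequence), srna_a)
  expect_true(all(cons$seed_predictor & cons$duplex_predictor))
  # pair-level subset property
  pairs <- function(x) unique(paste(x$sequence, x$gene_id))
  expect_true(all(pairs(cons) %in% intersect(pairs(seed), pairs(dup))))
})

test_that("AGO support needs peak overlap AND read presence, independently per AGO", {
  srna <- "TGAGGTAGTAGGTTGTATAGTT"
  utr <- paste0(strrep("A", 20), oracle_rc(srna), strrep("A", 20))
  tg <- toy_gene(utr)
  srnas <- srna_tbl(srna)
  cons <- consensus_sites(
    predict_seed_sites(srnas, tg$models, tg$genome),
    predict_duplex_sites(srnas, tg$models, tg$genome), tg$models)
  g <- cons$genomic[[1]]
  peak <- tibble::tibble(chrom = g$chrom[1], start = g$start[1] - 5L,
                         end = g$end[nrow(g)] + 5L, name = "p", score = 1,
                         strand = "+")
  far <- tibble::tibble(chrom = g$chrom[1], start = 1L, end = 20L,
                        name = "q", score = 1, strand = "+")
  out <- clip_support(cons,
                      ago_peaks = list(ago2 = peak, ago3 = far, ago1 = peak),
                      ago_reads = list(ago2 = srna, ago3 = srna,
                                       ago1 = character(0)))
  expect_true(out$ago2)            # peak + read
  expect_false(out$ago3)           # read but no overlapping peak
  expect_false(out$ago1)           # peak but sRNA absent from reads
  expect_false(out$ago4)           # no data at all
  expect_error(clip_support(cons, list(agoX = peak), list(agoX = srna)),
               "unknown AGO")
})

test_that("CLASH support respects the sRNA mismatch budget and slop window", {
  srna <- "TGAGGTAGTAGGTTGTATAGTT"
  utr <- paste0(strrep("A", 20), oracle_rc(srna), strrep("A", 20))
  tg <- toy_gene(utr)
  srnas <- srna_tbl(srna)
  cons <- consensus_sites(
    predict_seed_sites(srnas, tg$models, tg$genome),
    predict_duplex_sites(srnas, tg$models, tg$genome), tg$models)
  g <- cons$genomic[[1]]
  near <- srna; substr(near, 3, 3) <- "C"
  chim <- tibble::tibble(
    read_id = c("c1", "c2", "c3"),
    srna_seq = c(near, srna, srna),
    chrom = g$chrom[1],
    start = c(g$start[1], g$start[1] + 1040L, g$start[1] - 30L),
    end = c(g$end[1], g$start[1] + 1080L, g$start[1] - 10L),
    strand = "+")
  out <- clash_support(cons, chim[1, ], slop_nt = 25)
  expect_true(out$clash)           # 1-mm sRNA segment, overlapping fragment
  out2 <- clash_support(cons, chim[2, ], slop_nt = 25)
  expect_false(out2$clash)         # fragment ~1 kb away
  # slop monotonicity: a fragment just outside becomes reachable
  out3a <- clash_support(cons, chim[3, ], slop_nt = 0)
  out3b <- clash_support(cons, chim[3, ], slop_nt = 25)
  expect_false(out3a$clash)
  expect_true(out3b$clash)
})

test_that("antisense origin requires overlapping locus on the opposite strand", {
  srna <- "TGAGGTAGTAGGTTGTATAGTT"
  utr <- paste0(strrep("A", 20), oracle_rc(srna), strrep("A", 20))
  tg <- toy_gene(utr)   # plus-strand gene
  srnas <- srna_tbl(srna)
  cons <- consensus_sites(
    predict_seed_sites(srnas, tg$models, tg$genome),
    predict_duplex_sites(srnas, tg$models, tg$genome), tg$models)
  g <- cons$genomic[[1]]
  hit_minus <- tibble::tibble(sequence = srna, chrom = g$chrom[1],
                              start = g$start[1], end = g$end[1],
                              strand = "-", mismatches = 0L)
  hit_plus <- dplyr::mutate(hit_minus, strand = "+")
  expect_true(detect_antisense_origin(cons, hit_minus, tg$models)$antisense)
  expect_false(detect_antisense_origin(cons, hit_plus, tg$models)$antisense)
  # genome alignment of the sRNA over its own written site is the real case
  hits <- align_short_reads(srna, tg$genome, max_mm = 0, report_all = TRUE)
  expect_true(detect_antisense_origin(cons, hits, tg$models)$antisense)
})
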