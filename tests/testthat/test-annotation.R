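anno_fixture <- function() {
  # one plus-strand coding gene [100,850), intron [300,450); Alu copy inside
  # the intron [320,420); one ncRNA gene [900,1100); TAR at [150,200)
  models <- list(
    genes = tibble::tibble(
      gene_id = c("g1", "nc1"), chrom = "chrZ",
      start = c(100L, 900L), end = c(850L, 1100L), strand = "+",
      biotype = c("protein_coding", "lincRNA")),
    features = tibble::tibble(
      gene_id = c("g1", "g1", "g1", "nc1"),
      feature = c("exon", "exon", "intron", "exon"),
      chrom = "chrZ",
      start = c(100L, 450L, 300L, 900L),
      end = c(300L, 850L, 450L, 1100L),
      strand = "+"))
  repeats <- tibble::tibble(chrom = "chrZ", start = 320L, end = 420L,
                            strand = "+", family = "Alu",
                            consensus_offset = 30L, consensus_length = 300L)
  list(models = models, repeats = repeats)
}

hit <- function(seq, start, end, strand = "+") {
  tibble::tibble(sequence = seq, chrom = "chrZ", start = as.integer(start),
                 end = as.integer(end), strand = strand, mismatches = 0L)
}

test_that("locus classes follow the priority order with sense-matched genes", {
  fx <- anno_fixture()
  hits <- dplyr::bind_rows(
    hit("s_exon", 150, 170),        # coding exon
    hit("s_rep", 330, 350),         # Alu inside the intron: repeat wins
    hit("s_intron", 425, 445),      # intron outside the repeat
    hit("s_nc", 950, 970),          # ncRNA exon
    hit("s_inter", 2000, 2020),     # intergenic
    hit("s_anti", 150, 170, "-"))   # antisense over the exon
  cl <- classify_loci(hits, fx$models, fx$repeats)
  got <- setNames(cl$calls$primary_class, cl$calls$sequence)
  expect_equal(got[["s_exon"]], "exon")
  expect_equal(got[["s_rep"]], "repeat")
  expect_equal(got[["s_intron"]], "intron")
  expect_equal(got[["s_nc"]], "ncRNA")
  expect_equal(got[["s_inter"]], "intergenic")
  # an antisense locus over an exon is not an exonic origin
  expect_equal(got[["s_anti"]], "intergenic")
  expect_equal(cl$loci$repeat_family[cl$loci$sequence == "s_rep"], "Alu")
  # multi-locus sRNA: primary class is the highest priority across loci
  multi <- dplyr::bind_rows(hit("m", 425, 445), hit("m", 150, 170))
  cm <- classify_loci(multi, fx$models, fx$repeats)
  expect_equal(cm$calls$primary_class, "exon")
  expect_equal(cm$calls$class_set[[1]], c("exon", "intron"))
})

test_that("annotation percentages use the fixed denominator at 2 decimals", {
  a <- annotation_class_example()
  s <- summarize_annotation(a$counts, a$total_n)
  expect_equal(s$percentage[s$class == "repeat"], 45.20)
  expect_equal(s$percentage[s$class == "intron"], 47.39)
  expect_equal(s$percentage[s$class == "ncRNA"], 6.05)
  expect_equal(s$percentage[s$class == "exon"], 0.88)
  one <- summarize_annotation(c(intron = 50), total_n = 50)
  expect_equal(one$percentage, 100.00)
  # primary-mode percentages over calls sum to ~100
  fx <- anno_fixture()
  hits <- dplyr::bind_rows(hit("a", 150, 170), hit("b", 330, 350),
                           hit("c", 2000, 2020))
  cl <- classify_loci(hits, fx$models, fx$repeats)
  sp <- summarize_annotation(cl$calls)
  expect_equal(sum(sp$percentage), 100, tolerance = 0.02)
})

test_that("TAR overlap is strand-agnostic, half-open, and summarized over non-coding sRNAs", {
  fx <- anno_fixture()
  tar <- tibble::tibble(chrom = "chrZ", start = 150L, end = 200L,
                        name = "t1", score = 1, strand = "+")
  hits <- dplyr::bind_rows(
    hit("in_tar", 180, 199),
    hit("abut", 200, 220),          # abuts the TAR end: no overlap
    hit("off", 300, 320))
  cl <- classify_loci(hits, fx$models, fx$repeats)
  out <- tar_overlap(cl$calls, hits, tar, restrict_to_noncoding = FALSE)
  flag <- setNames(out$tar, out$sequence)
  expect_true(flag[["in_tar"]])
  expect_false(flag[["abut"]])
  expect_false(flag[["off"]])
  # restriction drops exon-class sRNAs from the denominator
  out2 <- tar_overlap(cl$calls, hits, tar, restrict_to_noncoding = TRUE)
  sm <- attr(out2, "summary")
  expect_equal(sm$n_denominator,
               sum(!vapply(cl$calls$class_set, function(cs) "exon" %in% cs,
                           logical(1))))
})

test_that("consensus profiles map hit starts through offset and orientation", {
  reps <- tibble::tibble(
    chrom = "chrZ", start = c(1000L, 2000L), end = c(1100L, 2100L),
    strand = c("+", "-"), family = "Alu",
    consensus_offset = c(30L, 30L), consensus_length = 300L)
  hits <- dplyr::bind_rows(
    hit("h_plus", 1010, 1030),            # pos 10 in + copy -> 30 + 10 = 40
    hit("h_minus", 2010, 2030))           # pos 10 in - copy -> 30 + 89 = 119
  w <- c(h_plus = 2, h_minus = 5)
  prof <- consensus_profile(hits, reps, w, "Alu")
  expect_equal(prof$weight[prof$position == 40], 2)
  expect_equal(prof$weight[prof$position == 30 + (100 - 1 - 10)], 5)
  # weight conservation (no out-of-range drops here)
  expect_equal(sum(prof$weight), sum(w))
  norm <- consensus_profile(hits, reps, w, "Alu", normalize = "sum_to_1")
  expect_equal(sum(norm$weight), 1, tolerance = 1e-9)
  # minus-strand hit: the 5' end sits at end - 1
  h2 <- hit("h_rev", 1010, 1030, "-")
  p2 <- consensus_profile(h2, reps, c(h_rev = 1), "Alu")
  expect_equal(p2$weight[p2$position == 30 + (1029 - 1000)], 1)
  # out-of-consensus positions are dropped with a counted warning
  reps_edge <- dplyr::mutate(reps[1, ], consensus_offset = 295L)
  expect_warning(pe <- consensus_profile(hits[1, ], reps_edge,
                                         w, "Alu"), "dropped")
  expect_equal(sum(pe$weight), 0)
  expect_error(consensus_profile(hits, reps, w, "L1"), "unknown")
})

test_that("per-position group tests detect planted shifts and respect label permutation", {
  set.seed(61)
  npos <- 40
  mk_prof <- function(sid, shift) {
    base <- rep(1, npos)
    if (shift) base[10] <- 6                 # planted shift at position 9
    wgt <- base + runif(npos, 0, 0.2)
    tibble::tibble(sample_id = sid, position = seq_len(npos) - 1L,
                   weight = wgt / sum(wgt))
  }
  profiles <- dplyr::bind_rows(
    lapply(sprintf("t%d", 1:4), mk_prof, shift = TRUE),
    lapply(sprintf("n%d", 1:4), mk_prof, shift = FALSE))
  res <- profile_group_test(profiles, sprintf("t%d", 1:4), sprintf("n%d", 1:4))
  expect_equal(res$position[which.min(res$q_bh)], 9)
  expect_true(attr(res, "summary")$n_significant >= 1)
  # permuting sample order within a group changes nothing
  res2 <- profile_group_test(profiles, sprintf("t%d", c(3, 1, 4, 2)),
                             sprintf("n%d", 1:4))
  expect_equal(res$p_value, res2$p_value)
  expect_error(profile_group_test(profiles, "t1", sprintf("n%d", 1:4)),
               "at least 2")
})
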