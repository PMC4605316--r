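test_that("generation is fully deterministic under a fixed configuration", {
  cfg <- small_gen_config(rng_seed = 77L)
  b1 <- suppressWarnings(simulate_bundle(cfg))
  b2 <- suppressWarnings(simulate_bundle(cfg))
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$read_sets, b2$read_sets)
  expect_identical(b1$chimeras, b2$chimeras)
  # a different seed gives different planted sequences
  b3 <- suppressWarnings(simulate_bundle(small_gen_config(rng_seed = 78L)))
  expect_false(identical(b1$truth$rsrnas$sequence, b3$truth$rsrnas$sequence))
})

test_that("planted rsRNAs are genome substrings with in-range lengths and real sites", {
  b <- small_bundle()
  tr <- b$truth$rsrnas
  expect_true(all(nchar(tr$sequence) >= 17 & nchar(tr$sequence) <= 28))
  expect_setequal(unique(tr$origin), c("intron", "repeat", "ncRNA", "hairpin"))
  for (i in seq_len(nrow(tr))) {
    # the planted sequence is the strand-adjusted substring of its locus
    got <- rsrnakit:::genome_seq(b$genome, tr$chrom[i], tr$start[i],
                                 tr$end[i], tr$strand[i])
    expect_equal(got, tr$sequence[i])
    # the seed complement (positions 2-8) occurs in the target 3' UTR
    utr_iv <- region_transcript_intervals(b$models, tr$target_gene[i],
                                          "three_utr")
    tx <- transcript_seq(b$models, b$genome, tr$target_gene[i])
    utr_seq <- substr(tx, utr_iv$t_start[1] + 1, utr_iv$t_end[nrow(utr_iv)])
    expect_true(grepl(oracle_rc(substr(tr$sequence[i], 2, 8)), utr_seq,
                      fixed = TRUE))
  }
})

test_that("repeat copies reconstruct from the recorded consensus substring", {
  b <- small_bundle()
  for (i in seq_len(nrow(b$repeats))) {
    rp <- b$repeats[i, ]
    rt <- b$repeat_truth[i, ]
    placed <- rsrnakit:::genome_seq(b$genome, rp$chrom, rp$start, rp$end, "+")
    want <- if (rp$strand == "+") rt$mutated_consensus else
      oracle_rc(rt$mutated_consensus)
    # planting later target sites never touches repeat loci
    expect_equal(placed, want)
    # the recorded substring differs from the consensus only at ~3% of bases
    cons_part <- substr(b$consensi[[rp$family]], rp$consensus_offset + 1,
                        rp$consensus_offset + (rp$end - rp$start))
    mm <- sum(strsplit(cons_part, "")[[1]] !=
                strsplit(rt$mutated_consensus, "")[[1]])
    expect_lte(mm, ceiling(0.06 * (rp$end - rp$start)))
    expect_gte(mm, 1)
  }
})

test_that("planted hairpin windows contain a detectable stem hosting the sRNA", {
  b <- small_bundle()
  cfg <- pipeline_config()
  hp_rsrnas <- b$truth$rsrnas[b$truth$rsrnas$origin == "hairpin", ]
  for (i in seq_len(nrow(hp_rsrnas))) {
    r <- hp_rsrnas[i, ]
    w0 <- r$start - cfg$flank_bp
    w1 <- r$end + cfg$flank_bp
    win <- rsrnakit:::genome_seq(b$genome, r$chrom, w0, w1)
    hp <- detect_hairpin(win, cfg$min_stem_pairs, cfg$min_loop_nt)
    expect_false(is.null(hp))
    expect_gte(hp$n_pairs, cfg$min_stem_pairs)
  }
})

test_that("decoy read counts match their designed failure modes", {
  b <- small_bundle()
  counts <- b$counts
  samples <- b$samples
  conds <- unique(samples$condition_id)
  cond_sum <- function(seq, cc) {
    cols <- samples$sample_id[samples$condition_id == cc]
    sum(unlist(counts[counts$sequence == seq, cols]))
  }
  dec <- b$truth$decoys
  for (s in dec$sequence[dec$failure_mode == "low_abundance"]) {
    expect_true(all(vapply(conds, function(cc) cond_sum(s, cc), numeric(1)) <= 4))
    expect_gte(sum(vapply(conds, function(cc) cond_sum(s, cc) >= 1,
                          logical(1))), 2)
  }
  for (s in dec$sequence[dec$failure_mode == "single_condition"]) {
    per <- vapply(conds, function(cc) cond_sum(s, cc), numeric(1))
    expect_equal(sum(per >= 1), 1)
    expect_gte(max(per), 5)
  }
  expect_true(all(dec$sequence[dec$failure_mode == "known_miRNA"] %in%
                    b$known_mirnas))
})

test_that("planted differential expression realizes near the configured fold change", {
  cfg <- small_gen_config(rng_seed = 31L, samples_per_group = 10L)
  ref <- generate_reference(cfg)
  pl <- plant_rsrnas(ref, cfg)
  sq <- simulate_sequencing(pl$truth, pl$reference, cfg)
  tr <- pl$truth$rsrnas
  up <- tr[tr$de_direction == "up_in_tumor", ]
  tcols <- sq$samples$sample_id[sq$samples$state == "tumor"]
  ncols <- sq$samples$sample_id[sq$samples$state == "normal"]
  ratios <- vapply(up$sequence, function(s) {
    row <- sq$counts[sq$counts$sequence == s, ]
    mean(unlist(row[tcols])) / mean(unlist(row[ncols]))
  }, numeric(1))
  # NB sampling error bounds around the planted 4x
  expect_true(all(ratios > 2.5 & ratios < 6))
})

test_that("interaction data covers planted pairs and spares decoys", {
  b <- small_bundle()
  tr <- b$truth$rsrnas
  all_peaks <- dplyr::bind_rows(b$ago_peaks)
  for (i in seq_len(nrow(tr))) {
    r <- tr[i, ]
    ov <- all_peaks$chrom == r$chrom &
      pmax(all_peaks$start, r$site_start) < pmin(all_peaks$end, r$site_end)
    expect_true(any(ov))
    expect_true(any(vapply(b$ago_reads, function(rd) r$sequence %in% rd,
                           logical(1))))
    expect_true(r$sequence %in% b$chimeras$srna_seq)
  }
  noint <- b$truth$decoys[b$truth$decoys$failure_mode == "no_interaction", ]
  expect_false(any(noint$sequence %in% unlist(b$ago_reads)))
  expect_false(any(noint$sequence %in% b$chimeras$srna_seq))
})

test_that("perturbation read sets recover every planted biogenesis label", {
  b <- small_bundle()
  p <- b$perturbations
  cfg <- pipeline_config()
  tr <- b$truth$rsrnas
  got <- vapply(seq_len(nrow(tr)), function(i) {
    s <- tr$sequence[i]
    dicer <- dependence_call(s, p$wt, p$dicer_kd, p$dicer_clip,
                             min_wt = cfg$min_reads)
    dgcr8 <- dependence_call(s, p$wt, p$dgcr8_kd, p$dgcr8_clip,
                             min_wt = cfg$min_reads)
    label_biogenesis(dicer, dgcr8)
  }, character(1))
  expect_equal(got, tr$biogenesis)
  # a Drosha/DGCR8-dependent plant is totally absent in the DGCR8 knockdown
  dep <- tr$sequence[tr$biogenesis == "drosha_dgcr8_dependent"]
  expect_true(all(vapply(dep, function(s) readset_presence(s, p$dgcr8_kd) == 0,
                         logical(1))))
  indep <- tr$sequence[tr$biogenesis == "independent"][1]
  expect_true(all(vapply(p, function(set) readset_presence(indep, set) > 0,
                         logical(1))))
})

test_that("planted anti-correlation is calibrated and nulls stay uncorrelated", {
  bm <- simulate_anticorr_benchmark(n_pairs = 200, n_samples = 30,
                                    r = -0.8, seed = 1)
  scr <- anticorrelation_screen(bm$srna_rpm, bm$expression, bm$pairs_planted)
  expect_gte(mean(scr$pass), 0.95)
  null <- anticorrelation_screen(bm$srna_rpm, bm$expression, bm$pairs_null)
  expect_lte(mean(null$pass), 0.05)
  expect_gte(mean(abs(null$r) < 0.5), 0.95)
  # zero noise: exactly r = -1
  x <- c(3, 9, 4, 12, 6)
  set.seed(2)
  y <- rsrnakit:::plant_anticorr_y(x, -1)
  expect_equal(cor(x, y), -1)
})
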