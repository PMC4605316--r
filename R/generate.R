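# Deterministic, seeded generator of every input the discovery cascade
# consumes, with a ground-truth ledger for recovery testing. The generator
# emulates the statistical structure the analysis assumes -- planted rsRNAs
# from introns, repeat copies, ncRNAs and hairpin precursors; decoy reads
# that each fail exactly one filter; AGO peaks/reads and CLASH chimeras
# covering planted interactions; WT/knockdown read sets encoding biogenesis
# dependence; expression matrices with planted anti-correlation -- not
# sequencing chemistry (no adapters, quality errors or PCR duplicates).

GENE_SPAN <- 750L
NCRNA_SPAN <- 300L
UTR3_LEN <- 300L

# Build one two-exon gene with intron, UTRs and CDS at genomic offset g.
make_gene <- function(gene_id, chrom, g, strand) {
  if (strand == "+") {
    ex <- list(c(g, g + 200L), c(g + 350L, g + 750L))
    intron <- c(g + 200L, g + 350L)
    utr5 <- c(g, g + 30L)
    cds <- list(c(g + 30L, g + 200L), c(g + 350L, g + 450L))
    utr3 <- c(g + 450L, g + 750L)
  } else {
    ex <- list(c(g + 550L, g + 750L), c(g, g + 400L))
    intron <- c(g + 400L, g + 550L)
    utr5 <- c(g + 720L, g + 750L)
    cds <- list(c(g + 550L, g + 720L), c(g + 300L, g + 400L))
    utr3 <- c(g, g + 300L)
  }
  feat <- function(feature, iv) {
    tibble::tibble(gene_id = gene_id, feature = feature, chrom = chrom,
                   start = iv[1], end = iv[2], strand = strand)
  }
  list(
    gene = tibble::tibble(gene_id = gene_id, chrom = chrom, start = g,
                          end = g + GENE_SPAN, strand = strand,
                          biotype = "protein_coding"),
    features = dplyr::bind_rows(
      feat("exon", ex[[1]]), feat("exon", ex[[2]]), feat("intron", intron),
      feat("five_utr", utr5), feat("cds", cds[[1]]), feat("cds", cds[[2]]),
      feat("three_utr", utr3)),
    intron = intron
  )
}

#' Generate the synthetic reference: genome, gene/repeat models, hairpins
#'
#' Produces a single-chromosome genome carrying two-exon protein-coding
#' genes (with introns and 3' UTRs), single-exon ncRNA genes, mutated copies
#' of per-family repeat consensi with recorded `(consensus_offset,
#' orientation)`, hairpin loci embedding a perfect-complement stem with all
#' three Microprocessor motifs at their configured positions, and a
#' synthetic known-miRNA catalog.
#'
#' @param config [generator_config()].
#' @param pconfig [pipeline_config()] (motif positions, stem/loop minima).
#' @return List: `genome`, `models`, `repeats`, `repeat_truth` (per-copy
#'   recorded mutated consensus substring), `hairpins` (per-locus window and
#'   precursor/loop coordinates), `consensi`, `known_mirnas`, `chrom`.
#' @export
generate_reference <- function(config = generator_config(),
                               pconfig = pipeline_config()) {
  set.seed(config$rng_seed)
  chrom <- "chrS"
  L <- config$genome_length
  genome <- setNames(random_dna(1, L), chrom)

  cursor <- 500L
  take <- function(len) {
    if (cursor + len > L - 500L) {
      stop("genome too short to place requested features; need at least ",
           cursor + len + 500L, " bp")
    }
    pos <- cursor
    cursor <<- cursor + len + 60L
    pos
  }

  genes <- list(); features <- list(); introns <- list()
  for (i in seq_len(config$n_genes)) {
    g <- take(GENE_SPAN)
    strand <- if (runif(1) < config$frac_minus_strand) "-" else "+"
    gm <- make_gene(sprintf("gene_%02d", i), chrom, g, strand)
    genes[[i]] <- gm$gene; features[[i]] <- gm$features
    introns[[i]] <- gm$intron
  }
  for (i in seq_len(config$n_ncrna)) {
    g <- take(NCRNA_SPAN)
    strand <- if (runif(1) < config$frac_minus_strand) "-" else "+"
    gid <- sprintf("ncrna_%02d", i)
    genes[[config$n_genes + i]] <- tibble::tibble(
      gene_id = gid, chrom = chrom, start = g, end = g + NCRNA_SPAN,
      strand = strand, biotype = "lincRNA")
    features[[config$n_genes + i]] <- tibble::tibble(
      gene_id = gid, feature = "exon", chrom = chrom, start = g,
      end = g + NCRNA_SPAN, strand = strand)
  }

  consensi <- list(Alu = random_dna(1, 300), ERVL = random_dna(1, 400))
  repeats <- list(); repeat_truth <- list()
  for (fam in names(consensi)) {
    clen <- nchar(consensi[[fam]])
    for (i in seq_len(config$n_repeat_copies)) {
      len <- sample(150:250, 1)
      off <- sample(0:(clen - len), 1)
      strand <- sample(c("+", "-"), 1)
      sub <- substr(consensi[[fam]], off + 1, off + len)
      # ~3% substitutions relative to the consensus
      chars <- strsplit(sub, "")[[1]]
      nmut <- max(1L, round(0.03 * len))
      at <- sample(len, nmut)
      chars[at] <- vapply(chars[at], function(ch) {
        sample(setdiff(DNA_CHARS, ch), 1)
      }, character(1))
      mutated <- paste(chars, collapse = "")
      g <- take(len)
      placed <- if (strand == "+") mutated else revcomp(mutated)
      genome <- genome_write(genome, chrom, g, placed)
      repeats[[length(repeats) + 1]] <- tibble::tibble(
        chrom = chrom, start = g, end = g + len, strand = strand,
        family = fam, consensus_offset = off, consensus_length = clen)
      repeat_truth[[length(repeat_truth) + 1]] <- tibble::tibble(
        family = fam, start = g, end = g + len, strand = strand,
        mutated_consensus = mutated)
    }
  }

  # hairpin loci: [14 nt basal context][arm5 30][loop 8][arm3 30][25 nt down]
  hairpins <- list()
  arm_len <- max(30L, pconfig$min_stem_pairs)
  for (i in seq_len(config$n_planted_per_origin)) {
    up <- random_dna(1, 14)
    substr(up, 1, 1) <- "T"   # offset -14 from precursor 5' end
    substr(up, 2, 2) <- "G"   # offset -13
    arm5 <- random_dna(1, arm_len)
    loop <- "CTGTAAGC"        # contains apical TGT (UGU)
    down <- random_dna(1, 25)
    substr(down, 17, 17) <- "C"  # CNNC start at downstream offset 17
    substr(down, 20, 20) <- "C"
    seqs <- paste0(up, arm5, loop, revcomp(arm5), down)
    g <- take(nchar(seqs))
    genome <- genome_write(genome, chrom, g, seqs)
    pre_start <- g + 14L
    pre_end <- pre_start + 2L * arm_len + nchar(loop)
    hairpins[[i]] <- tibble::tibble(
      chrom = chrom, locus_start = g, locus_end = g + nchar(seqs),
      pre_start = pre_start, pre_end = pre_end,
      arm5_start = pre_start, arm5_end = pre_start + arm_len,
      loop_start = pre_start + arm_len,
      loop_end = pre_start + arm_len + nchar(loop))
  }

  known <- unique(random_dna(config$n_known_mirnas, 22))

  list(genome = genome, chrom = chrom,
       models = list(genes = dplyr::bind_rows(genes),
                     features = dplyr::bind_rows(features)),
       introns = introns,
       repeats = dplyr::bind_rows(repeats),
       repeat_truth = dplyr::bind_rows(repeat_truth),
       hairpins = dplyr::bind_rows(hairpins),
       consensi = consensi,
       known_mirnas = known)
}

# write the reverse complement of the planted target site into a 3' UTR so
# the spliced transcript carries the full complement of the sRNA.
write_target_site <- function(reference, gene_id, srna_seq, utr_offset) {
  models <- reference$models
  iv <- region_transcript_intervals(models, gene_id, "three_utr")
  t0 <- iv$t_start[1] + utr_offset
  t1 <- t0 + nchar(srna_seq)
  stopifnot(t1 <= iv$t_end[nrow(iv)])
  blocks <- project_to_genome(models, gene_id, t0, t1)
  stopifnot(nrow(blocks) == 1)  # UTRs lie within one exon by construction
  strand <- blocks$strand[1]
  piece <- if (strand == "+") revcomp(srna_seq) else srna_seq
  reference$genome <- genome_write(reference$genome, blocks$chrom[1],
                                   blocks$start[1], piece)
  list(reference = reference,
       site = tibble::tibble(gene_id = gene_id, site_t_start = t0,
                             site_t_end = t1,
                             site_start = blocks$start[1],
                             site_end = blocks$end[1],
                             gene_strand = strand))
}

#' Plant rsRNAs, decoys and target sites; build the truth ledger
#'
#' Plants `n_planted_per_origin` rsRNAs per origin class (intron, repeat,
#' ncRNA, hairpin), each an exact substring of its stated locus with length
#' drawn from 17-28 nt and a full-complement target site written into a
#' protein-coding gene's 3' UTR; assigns biogenesis labels (hairpin plants
#' are Drosha/DGCR8-dependent, intron/ncRNA plants Dicer-only, repeat plants
#' independent); creates decoys per failure mode and the TAR interval set
#' covering `tar_fraction` of planted origin loci.
#'
#' @param reference Output of [generate_reference()].
#' @param config [generator_config()].
#' @param seed Integer seed (defaults to `config$rng_seed + 1`).
#' @return List: updated `reference` (genome now carries the target sites),
#'   `truth` (list of `rsrnas`, `decoys` tibbles), `tar` interval tibble.
#' @export
plant_rsrnas <- function(reference, config = generator_config(),
                         seed = config$rng_seed + 1L) {
  set.seed(seed)
  chrom <- reference$chrom
  npo <- config$n_planted_per_origin
  origins <- rep(c("intron", "repeat", "ncRNA", "hairpin"), each = npo)
  n_planted <- length(origins)
  used <- character(0)

  draw_locus <- function(origin, k) {
    len <- sample(17:28, 1)
    if (origin == "intron") {
      iv <- reference$introns[[config$n_genes - npo + k]]
      strand <- reference$models$genes$strand[config$n_genes - npo + k]
      start <- iv[1] + 20L + sample(0:(iv[2] - iv[1] - len - 20L), 1)
    } else if (origin == "repeat") {
      rp <- reference$repeats[k, ]  # k-th Alu copy
      strand <- rp$strand
      start <- rp$start + sample(0:(rp$end - rp$start - len), 1)
    } else if (origin == "ncRNA") {
      gi <- config$n_genes + k
      g <- reference$models$genes[gi, ]
      strand <- g$strand
      start <- g$start + sample(0:(g$end - g$start - len), 1)
    } else {
      hp <- reference$hairpins[k, ]
      strand <- "+"
      start <- hp$arm5_start + sample(0:(hp$arm5_end - hp$arm5_start - len), 1)
    }
    list(chrom = chrom, start = start, end = start + len, strand = strand)
  }

  rows <- list()
  for (i in seq_len(n_planted)) {
    origin <- origins[i]
    k <- ((i - 1L) %% npo) + 1L
    seqi <- NULL
    for (try in 1:20) {
      loc <- draw_locus(origin, k)
      s <- genome_seq(reference$genome, loc$chrom, loc$start, loc$end,
                      loc$strand)
      if (!(s %in% reference$known_mirnas) && !(s %in% used)) {
        seqi <- s
        break
      }
    }
    if (is.null(seqi)) stop("could not draw a collision-free rsRNA sequence")
    used <- c(used, seqi)
    target_gene <- sprintf("gene_%02d", i)
    ws <- write_target_site(reference, target_gene, seqi, 20L + 3L * (i %% 5))
    reference <- ws$reference
    biog <- switch(origin, hairpin = "drosha_dgcr8_dependent",
                   intron = "dicer_only", ncRNA = "dicer_only",
                   "independent")
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(srna_id = sprintf("rsrna_%02d", i), sequence = seqi,
                     origin = origin, chrom = loc$chrom, start = loc$start,
                     end = loc$end, strand = loc$strand, biogenesis = biog,
                     target_gene = target_gene, interaction = TRUE,
                     de_direction = if (i %% 5 == 0) "up_in_normal"
                                    else "up_in_tumor",
                     anticorr_target = target_gene),
      dplyr::select(ws$site, -"gene_id"))
  }
  rsrnas <- dplyr::bind_rows(rows)

  # TAR coverage: an exact fraction of planted origin loci
  n_tar <- round(config$tar_fraction * n_planted)
  tar_idx <- sort(sample(n_planted, n_tar))
  rsrnas$tar_covered <- seq_len(n_planted) %in% tar_idx
  tar <- tibble::tibble(
    chrom = rsrnas$chrom[tar_idx],
    start = pmax(0L, rsrnas$start[tar_idx] - 20L),
    end = rsrnas$end[tar_idx] + 20L,
    name = sprintf("tar_%02d", seq_len(n_tar)), score = 1, strand = "+")

  # decoys ------------------------------------------------------------------
  ndm <- config$n_decoys_per_mode
  rand_genome_seq <- function(len) {
    st <- sample(0:(config$genome_length - len - 1L), 1)
    genome_seq(reference$genome, chrom, st, st + len)
  }
  decoys <- list()
  for (j in seq_len(ndm)) {
    decoys[[length(decoys) + 1]] <- tibble::tibble(
      sequence = rand_genome_seq(sample(17:28, 1)),
      failure_mode = "low_abundance", target_gene = NA_character_)
    decoys[[length(decoys) + 1]] <- tibble::tibble(
      sequence = rand_genome_seq(sample(17:28, 1)),
      failure_mode = "single_condition", target_gene = NA_character_)
    decoys[[length(decoys) + 1]] <- tibble::tibble(
      sequence = reference$known_mirnas[j],
      failure_mode = "known_miRNA", target_gene = NA_character_)
  }
  # no_interaction decoys originate in introns and get real target sites,
  # so the interaction clause is the only one they fail
  for (j in seq_len(ndm)) {
    gi <- config$n_genes - 2L * npo + j  # introns distinct from planted ones
    iv <- reference$introns[[gi]]
    strand <- reference$models$genes$strand[gi]
    len <- sample(17:28, 1)
    st <- iv[1] + 10L + sample(0:(iv[2] - iv[1] - len - 10L), 1)
    s <- genome_seq(reference$genome, chrom, st, st + len, strand)
    target_gene <- sprintf("gene_%02d", n_planted + j)
    ws <- write_target_site(reference, target_gene, s, 20L)
    reference <- ws$reference
    decoys[[length(decoys) + 1]] <- tibble::tibble(
      sequence = s, failure_mode = "no_interaction",
      target_gene = target_gene)
  }
  decoys <- dplyr::bind_rows(decoys)

  list(reference = reference,
       truth = list(rsrnas = rsrnas, decoys = decoys),
       tar = tar)
}

#' Simulate small-RNA sequencing read sets and the expected count matrix
#'
#' Planted rsRNAs (and no_interaction decoys) receive negative-binomial
#' counts with the planted tumor:normal fold change in every condition;
#' low_abundance decoys total at most `min_reads - 1` per condition;
#' single_condition decoys are abundant in exactly one condition;
#' known_miRNA decoys duplicate catalog sequences; background sequences
#' appear at low rates from random genome positions.
#'
#' @param truth Truth ledger from [plant_rsrnas()].
#' @param reference Updated reference from [plant_rsrnas()].
#' @param config [generator_config()].
#' @param seed Integer seed (defaults to `config$rng_seed + 2`).
#' @return List: `read_sets` (named list per sample), `samples` metadata
#'   tibble, `counts` (the expected wide count matrix), `entities`
#'   (attribution of every sequence to a truth entity or background).
#' @export
simulate_sequencing <- function(truth, reference,
                                config = generator_config(),
                                seed = config$rng_seed + 2L) {
  set.seed(seed)
  conds <- sprintf("cond%d", seq_len(config$n_conditions))
  samples <- tidyr::expand_grid(
    condition_id = conds, state = c("tumor", "normal"),
    rep = seq_len(config$samples_per_group)) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_s%d", .data$condition_id,
                                      .data$state, .data$rep),
                  assay = "sRNA-seq") |>
    dplyr::select("sample_id", "condition_id", "state", "assay")

  draw <- function(mu) {
    if (config$noiseless_counts) as.integer(round(mu))
    else rnbinom(1, mu = mu, size = config$nb_size)
  }

  entities <- list(); count_rows <- list()
  add_entity <- function(sequence, type, counts) {
    entities[[length(entities) + 1]] <<- tibble::tibble(sequence = sequence,
                                                        type = type)
    count_rows[[length(count_rows) + 1]] <<-
      tibble::tibble(sequence = sequence, !!!setNames(as.list(counts),
                                                      samples$sample_id))
  }

  nb_profile <- function(direction) {
    vapply(seq_len(nrow(samples)), function(si) {
      mu <- config$nb_mean
      if (direction == "up_in_tumor" && samples$state[si] == "tumor") {
        mu <- mu * config$fold_change
      }
      if (direction == "up_in_normal" && samples$state[si] == "normal") {
        mu <- mu * config$fold_change
      }
      draw(mu)
    }, numeric(1))
  }

  for (i in seq_len(nrow(truth$rsrnas))) {
    add_entity(truth$rsrnas$sequence[i], "planted",
               nb_profile(truth$rsrnas$de_direction[i]))
  }
  for (i in seq_len(nrow(truth$decoys))) {
    d <- truth$decoys[i, ]
    counts <- numeric(nrow(samples))
    if (d$failure_mode == "low_abundance") {
      counts[which(samples$condition_id == conds[1])[1]] <- 2
      counts[which(samples$condition_id == conds[2])[1]] <- 2
    } else if (d$failure_mode == "single_condition") {
      idx <- which(samples$condition_id == conds[1])
      counts[idx[seq_len(min(3, length(idx)))]] <- c(4, 3, 3)[seq_len(min(3, length(idx)))]
    } else if (d$failure_mode == "known_miRNA") {
      counts <- nb_profile("none")
    } else {  # no_interaction: full planted-style expression
      counts <- nb_profile("up_in_tumor")
    }
    add_entity(d$sequence, paste0("decoy_", d$failure_mode), counts)
  }
  # stable abundant fraction (dominant miRNA/housekeeping-like sequences):
  # constant mean in both states, so library sizes stay comparable
  ab <- unique(vapply(seq_len(config$n_abundant_background), function(i) {
    len <- sample(20:24, 1)
    st <- sample(0:(config$genome_length - len - 1L), 1)
    genome_seq(reference$genome, reference$chrom, st, st + len)
  }, character(1)))
  for (s in ab) {
    counts <- vapply(seq_len(nrow(samples)), function(si) {
      draw(config$abundant_mean)
    }, numeric(1))
    add_entity(s, "abundant_background", counts)
  }
  bg <- unique(vapply(seq_len(config$n_background), function(i) {
    len <- sample(17:28, 1)
    st <- sample(0:(config$genome_length - len - 1L), 1)
    genome_seq(reference$genome, reference$chrom, st, st + len)
  }, character(1)))
  for (s in bg) {
    counts <- vapply(seq_len(nrow(samples)), function(si) {
      if (runif(1) < 0.3) 1 + stats::rpois(1, 0.5) else 0
    }, numeric(1))
    add_entity(s, "background", counts)
  }

  counts <- dplyr::bind_rows(count_rows)
  # a background draw may coincide with a planted sequence; keep first
  counts <- counts[!duplicated(counts$sequence), ]
  entities <- dplyr::bind_rows(entities)
  entities <- entities[!duplicated(entities$sequence), ]

  read_sets <- lapply(samples$sample_id, function(sid) {
    rep(counts$sequence, counts[[sid]])
  })
  names(read_sets) <- samples$sample_id
  list(read_sets = read_sets, samples = samples, counts = counts,
       entities = entities)
}

#' Simulate AGO CLIP peaks/read sets and CLASH chimeras
#'
#' Every interaction-supported planted pair gets peaks overlapping the
#' genomic site in two Argonautes (with the sRNA present in those read
#' sets) and a CLASH chimera joining the sRNA to a fragment overlapping the
#' site; no_interaction decoys get neither. A few background peaks and
#' chimeras are added.
#'
#' @param truth Truth ledger.
#' @param config [generator_config()].
#' @param seed Integer seed (defaults to `config$rng_seed + 3`).
#' @return List: `ago_peaks` (named list ago1..ago4 of interval tibbles),
#'   `ago_reads` (named list of read vectors), `chimeras` tibble.
#' @export
simulate_interaction_data <- function(truth, config = generator_config(),
                                      seed = config$rng_seed + 3L) {
  set.seed(seed)
  agos <- paste0("ago", 1:4)
  peaks <- setNames(vector("list", 4), agos)
  reads <- setNames(lapply(agos, function(a) character(0)), agos)
  chimeras <- list()
  supported <- truth$rsrnas[truth$rsrnas$interaction, ]
  for (i in seq_len(nrow(supported))) {
    r <- supported[i, ]
    chosen <- sample(agos, 2)
    for (a in chosen) {
      peaks[[a]][[length(peaks[[a]]) + 1]] <- tibble::tibble(
        chrom = r$chrom, start = max(0L, r$site_start - 10L),
        end = r$site_end + 10L, name = paste0(r$srna_id, "_", a),
        score = 100, strand = r$gene_strand)
      reads[[a]] <- c(reads[[a]], rep(r$sequence, 3))
    }
    chimeras[[length(chimeras) + 1]] <- tibble::tibble(
      read_id = paste0("chimera_", r$srna_id), srna_seq = r$sequence,
      chrom = r$chrom, start = max(0L, r$site_start - 5L),
      end = r$site_end + 5L, strand = r$gene_strand)
  }
  # background peaks/chimeras, attributable to the background class
  for (a in agos) {
    for (j in 1:3) {
      st <- sample(1000:(min(50000, 30000) * 1L), 1)
      peaks[[a]][[length(peaks[[a]]) + 1]] <- tibble::tibble(
        chrom = truth$rsrnas$chrom[1], start = st, end = st + 60L,
        name = sprintf("bg_%s_%d", a, j), score = 10, strand = "+")
    }
    peaks[[a]] <- dplyr::bind_rows(peaks[[a]])
  }
  for (j in 1:2) {
    st <- sample(1000:30000, 1)
    chimeras[[length(chimeras) + 1]] <- tibble::tibble(
      read_id = sprintf("chimera_bg_%d", j), srna_seq = random_dna(1, 21),
      chrom = truth$rsrnas$chrom[1], start = st, end = st + 40L,
      strand = "+")
  }
  list(ago_peaks = peaks, ago_reads = reads,
       chimeras = dplyr::bind_rows(chimeras))
}

#' Simulate WT/knockdown/CLIP read sets encoding biogenesis dependence
#'
#' Drosha/DGCR8-dependent rsRNAs are present in wild type and DGCR8/Dicer
#' CLIP but totally absent in DGCR8 and Drosha knockdowns; Dicer-only
#' rsRNAs are present in Dicer/TRBP CLIP and wild type, absent in Dicer
#' knockdown, and unaffected by Microprocessor knockdowns; independent
#' rsRNAs are present everywhere.
#'
#' @param truth Truth ledger.
#' @param config [generator_config()].
#' @param seed Integer seed (defaults to `config$rng_seed + 4`).
#' @return Named list of read vectors: `wt`, `dicer_kd`, `dgcr8_kd`,
#'   `drosha_kd`, `dicer_clip`, `trbp_clip`, `dgcr8_clip`.
#' @export
simulate_perturbations <- function(truth, config = generator_config(),
                                   seed = config$rng_seed + 4L) {
  set.seed(seed)
  sets <- list(wt = character(), dicer_kd = character(),
               dgcr8_kd = character(), drosha_kd = character(),
               dicer_clip = character(), trbp_clip = character(),
               dgcr8_clip = character())
  add <- function(set, s, n) {
    sets[[set]] <<- c(sets[[set]], rep(s, n))
  }
  entries <- dplyr::bind_rows(
    dplyr::select(truth$rsrnas, "sequence", "biogenesis"),
    tibble::tibble(sequence = truth$decoys$sequence,
                   biogenesis = "independent"))
  for (i in seq_len(nrow(entries))) {
    s <- entries$sequence[i]
    lab <- entries$biogenesis[i]
    add("wt", s, 10)
    if (lab == "drosha_dgcr8_dependent") {
      add("dicer_clip", s, 5); add("trbp_clip", s, 5); add("dgcr8_clip", s, 5)
      # dicer_kd, dgcr8_kd, drosha_kd: absent
    } else if (lab == "dicer_only") {
      add("dicer_clip", s, 5); add("trbp_clip", s, 5)
      add("dgcr8_kd", s, 10); add("drosha_kd", s, 10)
    } else {
      add("dicer_kd", s, 10); add("dgcr8_kd", s, 10); add("drosha_kd", s, 10)
      add("dicer_clip", s, 5); add("trbp_clip", s, 5); add("dgcr8_clip", s, 5)
    }
  }
  sets
}

# y anti-correlated with x at target Pearson r (negative): decreasing affine
# function plus Gaussian noise with sd calibrated from the variance of x.
plant_anticorr_y <- function(x, r, slope = 1) {
  stopifnot(r < 0, r >= -1)
  sd_x <- sd(x)
  sd_noise <- if (r == -1 || sd_x == 0) 0 else {
    slope * sd_x * sqrt(1 / r^2 - 1)
  }
  y <- -slope * x + rnorm(length(x), 0, sd_noise)
  y <- y - min(y) + 10  # shift positive (location does not affect r)
  y
}

#' Simulate gene RPKM and protein abundance matrices
#'
#' For each planted anti-correlation pair the target's expression is a
#' decreasing affine function of the rsRNA's RPM plus Gaussian noise
#' calibrated so the realized Pearson r concentrates at the configured
#' value; all other genes are independent of sRNA levels.
#'
#' @param truth Truth ledger.
#' @param counts Expected count matrix from [simulate_sequencing()].
#' @param reference Reference (gene catalog).
#' @param config [generator_config()].
#' @param seed Integer seed (defaults to `config$rng_seed + 5`).
#' @return List: `rpkm` (all genes x samples), `protein` (subset of genes).
#' @export
simulate_expression <- function(truth, counts, reference,
                                config = generator_config(),
                                seed = config$rng_seed + 5L) {
  set.seed(seed)
  rpm <- rpm_normalize(counts)
  sample_ids <- matrix_samples(rpm)
  gene_ids <- reference$models$genes$gene_id[
    reference$models$genes$biotype == "protein_coding"]
  target_of <- setNames(truth$rsrnas$sequence, truth$rsrnas$anticorr_target)
  rows <- lapply(gene_ids, function(g) {
    if (g %in% names(target_of)) {
      x <- as.numeric(rpm[rpm$sequence == target_of[[g]], sample_ids])
      y <- plant_anticorr_y(x, config$anticorr_r)
    } else {
      y <- stats::rlnorm(length(sample_ids), log(50), 0.5)
    }
    tibble::tibble(gene_id = g, !!!setNames(as.list(y), sample_ids))
  })
  rpkm <- dplyr::bind_rows(rows)
  protein_genes <- gene_ids[seq_len(min(10, length(gene_ids)))]
  prot <- rpkm[rpkm$gene_id %in% protein_genes, ]
  list(rpkm = rpkm, protein = prot)
}

#' Benchmark set of planted anti-correlated and null pairs
#'
#' Standalone calibration harness for the anti-correlation screen: draws
#' sRNA RPM-like profiles, plants targets at the requested correlation, and
#' pairs an equal number of independent null genes.
#'
#' @param n_pairs Planted (and null) pairs.
#' @param n_samples Samples per profile.
#' @param r Planted correlation (negative).
#' @param seed Integer seed.
#' @return List: `srna_rpm`, `expression`, `pairs_planted`, `pairs_null`.
#' @export
simulate_anticorr_benchmark <- function(n_pairs = 200, n_samples = 30,
                                        r = -0.8, seed = 1L) {
  set.seed(seed)
  srna_ids <- sprintf("SRNA%03d", seq_len(n_pairs))
  sample_ids <- sprintf("s%02d", seq_len(n_samples))
  xs <- lapply(seq_len(n_pairs), function(i) stats::rlnorm(n_samples, log(100), 0.6))
  srna_rpm <- dplyr::bind_rows(lapply(seq_len(n_pairs), function(i) {
    tibble::tibble(sequence = srna_ids[i],
                   !!!setNames(as.list(xs[[i]]), sample_ids))
  }))
  planted <- dplyr::bind_rows(lapply(seq_len(n_pairs), function(i) {
    tibble::tibble(gene_id = sprintf("T%03d", i),
                   !!!setNames(as.list(plant_anticorr_y(xs[[i]], r)),
                               sample_ids))
  }))
  nulls <- dplyr::bind_rows(lapply(seq_len(n_pairs), function(i) {
    tibble::tibble(gene_id = sprintf("N%03d", i),
                   !!!setNames(as.list(stats::rlnorm(n_samples, log(50), 0.5)),
                               sample_ids))
  }))
  list(srna_rpm = srna_rpm,
       expression = dplyr::bind_rows(planted, nulls),
       pairs_planted = tibble::tibble(sequence = srna_ids,
                                      gene_id = sprintf("T%03d", seq_len(n_pairs))),
       pairs_null = tibble::tibble(sequence = srna_ids,
                                   gene_id = sprintf("N%03d", seq_len(n_pairs))))
}

#' Generate the complete synthetic study bundle
#'
#' Runs the whole generator chain (reference, planting, sequencing,
#' interaction data, perturbations, expression) under one configuration and
#' seed, returning every input [run_pipeline()] consumes plus the truth
#' ledger.
#'
#' @param config [generator_config()].
#' @param pconfig [pipeline_config()].
#' @return List of class `rsrna_bundle`.
#' @export
simulate_bundle <- function(config = generator_config(),
                            pconfig = pipeline_config()) {
  reference <- generate_reference(config, pconfig)
  pl <- plant_rsrnas(reference, config)
  reference <- pl$reference
  seqs <- simulate_sequencing(pl$truth, reference, config)
  inter <- simulate_interaction_data(pl$truth, config)
  pert <- simulate_perturbations(pl$truth, config)
  expr <- simulate_expression(pl$truth, seqs$counts, reference, config)
  structure(list(
    genome = reference$genome, chrom = reference$chrom,
    models = reference$models, repeats = reference$repeats,
    repeat_truth = reference$repeat_truth, hairpins = reference$hairpins,
    consensi = reference$consensi, known_mirnas = reference$known_mirnas,
    tar = pl$tar, truth = pl$truth,
    read_sets = seqs$read_sets, samples = seqs$samples,
    counts = seqs$counts, entities = seqs$entities,
    ago_peaks = inter$ago_peaks, ago_reads = inter$ago_reads,
    chimeras = inter$chimeras, perturbations = pert,
    expression = expr, config = config
  ), class = "rsrna_bundle")
}

#' Write a synthetic bundle to disk in standard formats
#'
#' Serializes the bundle as the formats the readers consume: genome FASTA,
#' models GFF3, TAR/peak BED6, per-sample read FASTA, chimera and
#' count/expression TSVs, truth-ledger TSV and a JSON manifest.
#'
#' @param bundle Output of [simulate_bundle()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_sequences(setNames(bundle$genome, names(bundle$genome)), fp("genome.fa"))
  write_models(bundle$models, bundle$repeats, fp("models.gff3"))
  write_bed(bundle$tar, fp("tar.bed"))
  write_sequences(setNames(bundle$known_mirnas,
                           sprintf("mir_%03d", seq_along(bundle$known_mirnas))),
                  fp("known_mirnas.fa"))
  dir.create(fp("reads"), showWarnings = FALSE)
  for (sid in names(bundle$read_sets)) {
    rs <- bundle$read_sets[[sid]]
    write_sequences(setNames(rs, sprintf("%s_r%05d", sid, seq_along(rs))),
                    fp("reads", paste0(sid, ".fa")))
  }
  for (a in names(bundle$ago_peaks)) {
    write_bed(bundle$ago_peaks[[a]], fp(paste0(a, "_peaks.bed")))
    rs <- bundle$ago_reads[[a]]
    write_sequences(setNames(rs, sprintf("%s_r%05d", a, seq_along(rs))),
                    fp(paste0(a, "_reads.fa")))
  }
  write_table_tsv(bundle$chimeras, fp("chimeras.tsv"))
  write_table_tsv(bundle$counts, fp("counts.tsv"))
  write_table_tsv(bundle$samples, fp("samples.tsv"))
  write_table_tsv(bundle$expression$rpkm, fp("rpkm.tsv"))
  write_table_tsv(bundle$expression$protein, fp("protein.tsv"))
  write_table_tsv(bundle$truth$rsrnas, fp("truth_rsrnas.tsv"))
  write_table_tsv(bundle$truth$decoys, fp("truth_decoys.tsv"))
  jsonlite::write_json(
    list(seed = bundle$config$rng_seed,
         config = unclass(bundle$config),
         n_planted = nrow(bundle$truth$rsrnas),
         n_decoys = nrow(bundle$truth$decoys),
         n_samples = nrow(bundle$samples)),
    fp("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
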