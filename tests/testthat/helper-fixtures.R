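# Shared fixtures: a reduced-scale generator configuration plus cached
# bundles/pipeline runs so the expensive end-to-end objects are built once
# per session.

small_gen_config <- function(rng_seed = 11L, ...) {
  generator_config(
    genome_length = 40000L, n_genes = 18L, n_ncrna = 4L,
    n_repeat_copies = 4L, n_planted_per_origin = 3L, n_decoys_per_mode = 3L,
    n_known_mirnas = 20L, n_background = 30L, n_abundant_background = 8L,
    rng_seed = rng_seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

small_bundle <- function() {
  cached("small_bundle",
         suppressWarnings(simulate_bundle(small_gen_config())))
}

small_bundle_noiseless <- function() {
  cached("small_bundle_noiseless",
         suppressWarnings(simulate_bundle(
           small_gen_config(rng_seed = 12L, noiseless_counts = TRUE))))
}

small_pipeline <- function() {
  cached("small_pipeline",
         suppressWarnings(run_pipeline(small_bundle(), pipeline_config())))
}

# one hand-built plus-strand gene whose 3' UTR sequence is fully controlled:
# transcript = exon1(60) + exon2(140); 3' UTR = last utr_len bases of exon2
toy_gene <- function(utr_seq, gene_id = "g1", strand = "+",
                     pad = "left") {
  utr_len <- nchar(utr_seq)
  stopifnot(utr_len <= 140)
  set.seed(99)
  ex2_prefix <- 140 - utr_len
  if (strand == "+") {
    exon1 <- c(100L, 160L); exon2 <- c(220L, 360L)
    utr3 <- c(360L - utr_len, 360L)
  } else {
    exon1 <- c(220L, 280L)                     # 5' exon (rightmost)
    exon2 <- c(40L, 180L)                      # 3' exon
    utr3 <- c(40L, 40L + utr_len)
  }
  genome <- setNames(paste(sample(c("A", "C", "G", "T"), 420, replace = TRUE),
                           collapse = ""), "chrT")
  models <- list(
    genes = tibble::tibble(gene_id = gene_id, chrom = "chrT",
                           start = min(exon1[1], exon2[1]),
                           end = max(exon1[2], exon2[2]), strand = strand,
                           biotype = "protein_coding"),
    features = tibble::tibble(
      gene_id = gene_id,
      feature = c("exon", "exon", "three_utr"),
      chrom = "chrT",
      start = c(exon1[1], exon2[1], utr3[1]),
      end = c(exon1[2], exon2[2], utr3[2]),
      strand = strand))
  # write the UTR sequence into the genome so the transcript carries utr_seq
  piece <- if (strand == "+") utr_seq else oracle_rc(utr_seq)
  g <- genome[["chrT"]]
  substr(g, utr3[1] + 1, utr3[2]) <- piece
  genome[["chrT"]] <- g
  list(genome = genome, models = models)
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
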