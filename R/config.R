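#' Pipeline configuration
#'
#' Bundles every tunable threshold of the discovery cascade. Defaults encode
#' the study conditions: reads must reach `min_reads` copies within at least
#' one experimental condition and be present in at least `min_conditions`
#' distinct conditions; genome mapping and sRNA:target duplexes tolerate at
#' most two substitutions; hairpin analysis extracts `flank_bp` of context on
#' each side of the candidate; differential expression requires a two-fold
#' change in at least one condition; anti-correlation screening requires
#' Pearson r at or below `pcc_max` with p at or below `p_max`.
#'
#' @param min_reads Minimum summed read count within a single condition.
#' @param min_conditions Minimum number of distinct conditions with presence.
#' @param max_genome_mismatches Substitutions tolerated in genome alignment.
#' @param max_duplex_mismatches Substitutions tolerated in the sRNA:target duplex.
#' @param flank_bp Flanking bases extracted around a candidate for hairpin and
#'   motif analysis (the analyzed window is the sRNA locus plus `flank_bp` on
#'   each side).
#' @param fold_change_min Minimum tumor/normal fold change (either direction).
#' @param pcc_max Maximum (most positive) Pearson r accepted as anti-correlation;
#'   must be negative.
#' @param p_max Significance threshold for correlation p-values.
#' @param pseudocount Added to mean RPM in fold-change ratios.
#' @param cnnc_center Expected offset (nt downstream of the precursor 3' end,
#'   first downstream base = 1) of the CNNC motif start.
#' @param cnnc_tolerance Allowed deviation (nt) around `cnnc_center`.
#' @param basal_u_pos,basal_g_pos Offsets (negative, upstream of the precursor
#'   5' end, immediately preceding base = -1) of the basal U and G.
#' @param stem_tolerance_nt Bases of an sRNA allowed to fall outside a hairpin
#'   arm while still counting as stem-placed.
#' @param min_stem_pairs Minimum paired bases for a reported hairpin.
#' @param min_loop_nt Minimum hairpin loop length.
#' @param clash_slop_nt Slop added to each side of a site when matching CLASH
#'   target fragments.
#' @param rng_seed Integer seed recorded in run manifests.
#' @return A list of class `rsrna_config`.
#' @export
pipeline_config <- function(min_reads = 5L,
                            min_conditions = 2L,
                            max_genome_mismatches = 2L,
                            max_duplex_mismatches = 2L,
                            flank_bp = 100L,
                            fold_change_min = 2,
                            pcc_max = -0.5,
                            p_max = 0.05,
                            pseudocount = 0.5,
                            cnnc_center = 17L,
                            cnnc_tolerance = 2L,
                            basal_u_pos = -14L,
                            basal_g_pos = -13L,
                            stem_tolerance_nt = 2L,
                            min_stem_pairs = 16L,
                            min_loop_nt = 3L,
                            clash_slop_nt = 25L,
                            rng_seed = 1L) {
  cfg <- list(
    min_reads = as.integer(min_reads),
    min_conditions = as.integer(min_conditions),
    max_genome_mismatches = as.integer(max_genome_mismatches),
    max_duplex_mismatches = as.integer(max_duplex_mismatches),
    flank_bp = as.integer(flank_bp),
    fold_change_min = fold_change_min,
    pcc_max = pcc_max,
    p_max = p_max,
    pseudocount = pseudocount,
    cnnc_center = as.integer(cnnc_center),
    cnnc_tolerance = as.integer(cnnc_tolerance),
    basal_u_pos = as.integer(basal_u_pos),
    basal_g_pos = as.integer(basal_g_pos),
    stem_tolerance_nt = as.integer(stem_tolerance_nt),
    min_stem_pairs = as.integer(min_stem_pairs),
    min_loop_nt = as.integer(min_loop_nt),
    clash_slop_nt = as.integer(clash_slop_nt),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$min_reads >= 1, cfg$min_conditions >= 1,
    cfg$max_genome_mismatches >= 0, cfg$max_duplex_mismatches >= 0,
    cfg$flank_bp > 0, cfg$fold_change_min > 0, cfg$pcc_max < 0,
    cfg$p_max > 0, cfg$pseudocount > 0, cfg$min_stem_pairs > 0,
    cfg$min_loop_nt > 0, cfg$clash_slop_nt >= 0
  )
  structure(cfg, class = "rsrna_config")
}

#' Synthetic-data generator configuration
#'
#' Controls the scale and signal strength of the synthetic study. Defaults
#' emulate a desk-scale version of the study conditions: several cancer
#' conditions each with tumor and normal samples, negative-binomial sRNA
#' counts, planted rsRNAs with four-fold differential expression, and
#' anti-correlated target expression near Pearson r = -0.8.
#'
#' @param genome_length Length of the single synthetic chromosome.
#' @param n_genes Number of protein-coding genes (each with two exons, an
#'   intron, and a 3' UTR long enough to host planted target sites).
#' @param n_ncrna Number of single-exon non-coding RNA genes.
#' @param n_repeat_copies Mutated copies generated per repeat family.
#' @param n_planted_per_origin Planted rsRNAs for each origin class
#'   (intron, repeat, ncRNA, hairpin).
#' @param n_decoys_per_mode Decoy reads per failure mode
#'   (low_abundance, single_condition, known_miRNA, no_interaction).
#' @param n_known_mirnas Size of the synthetic known-miRNA catalog.
#' @param n_background Distinct low-rate background sequences drawn from
#'   random genome positions.
#' @param n_abundant_background Distinct constant, highly abundant background
#'   sequences (the stable library fraction real small-RNA libraries are
#'   dominated by -- abundant miRNAs and housekeeping ncRNA fragments); keeps
#'   library composition comparable between states so RPM fold changes track
#'   count fold changes.
#' @param abundant_mean Mean count per sample of each abundant background
#'   sequence.
#' @param n_conditions Number of experimental conditions (cancer types).
#' @param samples_per_group Samples per condition x state cell.
#' @param nb_mean,nb_size Negative-binomial mean and size (dispersion) for
#'   expressed sRNA counts.
#' @param fold_change Planted tumor:normal fold change for differential
#'   rsRNAs.
#' @param anticorr_r Target Pearson correlation for planted rsRNA:target
#'   anti-correlation (negative).
#' @param tar_fraction Fraction of planted loci covered by transcriptionally
#'   active regions.
#' @param frac_minus_strand Probability a gene is placed on the minus strand.
#' @param noiseless_counts If `TRUE`, sRNA counts are deterministic (exact
#'   planted means) rather than negative-binomial draws.
#' @param rng_seed Integer seed; identical configurations and seeds give
#'   byte-identical bundles.
#' @return A list of class `rsrna_gen_config`.
#' @export
generator_config <- function(genome_length = 60000L,
                             n_genes = 30L,
                             n_ncrna = 6L,
                             n_repeat_copies = 6L,
                             n_planted_per_origin = 5L,
                             n_decoys_per_mode = 5L,
                             n_known_mirnas = 40L,
                             n_background = 80L,
                             n_abundant_background = 15L,
                             abundant_mean = 1000,
                             n_conditions = 4L,
                             samples_per_group = 3L,
                             nb_mean = 50,
                             nb_size = 10,
                             fold_change = 4,
                             anticorr_r = -0.8,
                             tar_fraction = 0.7,
                             frac_minus_strand = 0.3,
                             noiseless_counts = FALSE,
                             rng_seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    n_ncrna = as.integer(n_ncrna),
    n_repeat_copies = as.integer(n_repeat_copies),
    n_planted_per_origin = as.integer(n_planted_per_origin),
    n_decoys_per_mode = as.integer(n_decoys_per_mode),
    n_known_mirnas = as.integer(n_known_mirnas),
    n_background = as.integer(n_background),
    n_abundant_background = as.integer(n_abundant_background),
    abundant_mean = abundant_mean,
    n_conditions = as.integer(n_conditions),
    samples_per_group = as.integer(samples_per_group),
    nb_mean = nb_mean,
    nb_size = nb_size,
    fold_change = fold_change,
    anticorr_r = anticorr_r,
    tar_fraction = tar_fraction,
    frac_minus_strand = frac_minus_strand,
    noiseless_counts = isTRUE(noiseless_counts),
    rng_seed = as.integer(rng_seed)
  )
  stopifnot(
    cfg$genome_length > 1000,
    cfg$n_genes >= cfg$n_planted_per_origin * 6,
    cfg$n_decoys_per_mode <= cfg$n_planted_per_origin,
    cfg$n_conditions >= 2, cfg$samples_per_group >= 1,
    cfg$nb_mean > 0, cfg$nb_size > 0, cfg$fold_change >= 1,
    cfg$anticorr_r < 0, cfg$anticorr_r > -1 || cfg$anticorr_r == -1,
    cfg$tar_fraction >= 0, cfg$tar_fraction <= 1
  )
  structure(cfg, class = "rsrna_gen_config")
}
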