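# End-to-end orchestration of the discovery cascade and the recurrence
# spectrum report. Stage order follows the study workflow: catalog filters,
# target consensus, interaction validation, differential expression, then
# biogenesis/correlation/annotation layers for the surviving candidates.
# Every clause is conjunctive, so the final candidate set is independent of
# stage order; the order only shapes the per-stage rejection attribution.

#' Run the full rsRNA discovery cascade
#'
#' Executes: unique-read collapsing, known-miRNA exclusion,
#' abundance/recurrence filters, genome alignment, dual-predictor target
#' consensus, AGO CLIP / CLASH interaction validation, fold-change
#' differential expression, and -- for surviving candidates -- biogenesis
#' profiling, anti-correlation screening and genomic annotation. Every
#' catalog sequence appears exactly once in the output with a final status
#' (`potential_rsRNA` or `rejected:<stage>`).
#'
#' @param bundle Input bundle: a list with `read_sets`, `samples`, `genome`,
#'   `models`, `repeats`, `known_mirnas`, `ago_peaks`, `ago_reads`,
#'   `chimeras`, `perturbations`, `expression`, `tar` (as produced by
#'   [simulate_bundle()], or assembled from files via the readers). Optional
#'   layers (`perturbations`, `expression$protein`, `tar`) may be `NULL`;
#'   the corresponding columns degrade to `NA`.
#' @param config [pipeline_config()].
#' @return A tibble of class `rsrna_pipeline`, one row per catalog sequence,
#'   with attributes `stages` (stage-by-stage survivor counts), `sites`
#'   (validated consensus sites) and `manifest` (config echo, seed, input
#'   sizes).
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  counts_all <- collapse_reads(bundle$read_sets, bundle$samples)
  stage <- list(input_sequences = nrow(counts_all))

  counts_known <- exclude_known_mirnas(counts_all, bundle$known_mirnas)
  known_excluded <- attr(counts_known, "excluded")
  stage$after_known_mirna <- nrow(counts_known)

  counts_f <- apply_presence_filters(counts_known, bundle$samples,
                                     config$min_reads, config$min_conditions)
  diags <- attr(counts_f, "diagnostics")
  stage$after_presence_filters <- nrow(counts_f)

  hits_all <- align_short_reads(counts_f$sequence, bundle$genome,
                                config$max_genome_mismatches,
                                report_all = TRUE)
  mapped <- unique(hits_all$sequence)
  stage$after_mapping <- length(mapped)

  srnas <- tibble::tibble(sequence = sort(mapped))
  srnas$srna_id <- sprintf("srna_%04d", seq_len(nrow(srnas)))

  seed_sites <- predict_seed_sites(srnas, bundle$models, bundle$genome)
  duplex_sites <- predict_duplex_sites(srnas, bundle$models, bundle$genome,
                                       config$max_duplex_mismatches)
  sites <- consensus_sites(seed_sites, duplex_sites, bundle$models)
  targeted <- unique(sites$sequence)
  stage$after_target_consensus <- length(targeted)

  sites <- clip_support(sites, bundle$ago_peaks, bundle$ago_reads)
  sites <- clash_support(sites, bundle$chimeras, config$clash_slop_nt)
  sites <- detect_antisense_origin(sites, hits_all, bundle$models)
  ago_cols <- paste0("ago", 1:4)
  site_support <- sites |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      n_consensus_targets = dplyr::n_distinct(.data$gene_id),
      dplyr::across(dplyr::all_of(c(ago_cols, "clash", "antisense")), any),
      .groups = "drop")
  interacting <- site_support$sequence[
    rowSums(as.matrix(site_support[, c(ago_cols, "clash")])) > 0]
  stage$after_interaction <- length(interacting)

  # RPM over the full library (known miRNAs included in the denominator)
  rpm <- rpm_normalize(counts_all)
  fc_calls <- fold_change_flags(rpm[rpm$sequence %in% interacting, ],
                                bundle$samples, config$fold_change_min,
                                config$pseudocount)
  de <- de_flags(fc_calls)
  final_seqs <- de$sequence[de$de]
  stage$potential_rsRNA <- length(final_seqs)

  # annotation layers for final candidates ----------------------------------
  cand <- srnas[srnas$sequence %in% final_seqs, ]
  biog <- if (!is.null(bundle$perturbations) && nrow(cand) > 0) {
    biogenesis_profile(cand, hits_all[hits_all$sequence %in% cand$sequence, ],
                       bundle$genome, bundle$perturbations, config)
  } else NULL
  anno <- if (nrow(cand) > 0) {
    cl <- classify_loci(hits_all[hits_all$sequence %in% cand$sequence, ],
                        bundle$models, bundle$repeats)
    if (!is.null(bundle$tar)) tar_overlap(cl$calls, hits_all, bundle$tar)
    else cl$calls
  } else NULL
  anti <- NULL
  if (!is.null(bundle$expression) && nrow(cand) > 0) {
    pairs <- dplyr::distinct(sites[sites$sequence %in% final_seqs, ],
                             .data$sequence, .data$gene_id)
    if (nrow(pairs) > 0) {
      scr_rna <- anticorrelation_screen(rpm, bundle$expression$rpkm, pairs,
                                        config$pcc_max, config$p_max)
      anti <- scr_rna |>
        dplyr::group_by(.data$sequence) |>
        dplyr::summarise(n_anticorr_rnaseq = sum(.data$pass), .groups = "drop")
      if (!is.null(bundle$expression$protein)) {
        prot_pairs <- pairs[pairs$gene_id %in% bundle$expression$protein$gene_id, ]
        if (nrow(prot_pairs) > 0) {
          scr_prot <- anticorrelation_screen(rpm, bundle$expression$protein,
                                             prot_pairs, config$pcc_max,
                                             config$p_max)
          anti <- dplyr::left_join(
            anti,
            dplyr::summarise(dplyr::group_by(scr_prot, .data$sequence),
                             n_anticorr_protein = sum(.data$pass),
                             .groups = "drop"),
            by = "sequence")
        }
      }
    }
  }

  # assemble one record per catalog sequence --------------------------------
  records <- tibble::tibble(sequence = counts_all$sequence)
  records$known_mirna <- records$sequence %in% known_excluded
  records <- dplyr::left_join(records, diags, by = "sequence")
  records$mapped <- records$sequence %in% mapped
  records <- dplyr::left_join(records, site_support, by = "sequence")
  records$n_consensus_targets[is.na(records$n_consensus_targets) &
                                records$sequence %in% mapped] <- 0L
  records <- dplyr::left_join(records, de[, c("sequence", "de")],
                              by = "sequence")
  records$status <- dplyr::case_when(
    records$known_mirna ~ "rejected:known_mirna",
    !records$pass_abundance ~ "rejected:abundance",
    !records$pass_recurrence ~ "rejected:recurrence",
    !records$mapped ~ "rejected:unmapped",
    is.na(records$n_consensus_targets) | records$n_consensus_targets == 0 ~
      "rejected:no_target",
    !records$sequence %in% interacting ~ "rejected:no_interaction",
    !records$de | is.na(records$de) ~ "rejected:not_differential",
    TRUE ~ "potential_rsRNA")
  records <- dplyr::left_join(records,
                              srnas[, c("sequence", "srna_id")],
                              by = "sequence")
  if (!is.null(biog)) {
    records <- dplyr::left_join(
      records, dplyr::select(biog, -"srna_id"), by = "sequence")
  }
  if (!is.null(anno)) {
    records <- dplyr::left_join(records, anno, by = "sequence")
  }
  if (!is.null(anti)) {
    records <- dplyr::left_join(records, anti, by = "sequence")
  }
  records <- dplyr::relocate(records, "srna_id", "sequence", "status")

  stage_names <- names(stage)
  stage_n <- as.integer(unlist(stage, use.names = FALSE))
  attr(records, "stages") <- tibble::tibble(stage = stage_names, n = stage_n)
  attr(records, "sites") <- sites
  attr(records, "manifest") <- list(
    config = unclass(config),
    seed = config$rng_seed,
    n_samples = nrow(bundle$samples),
    n_input_sequences = nrow(counts_all),
    timestamp = NA_character_)
  class(records) <- c("rsrna_pipeline", class(records))
  records
}

#' Recurrence spectrum with interaction-association fractions
#'
#' For each recurrence level k, the number of sequences present (count >= 1)
#' in at least k conditions, split into the fraction with any AGO/CLASH
#' association and the fraction without.
#'
#' @param counts Wide count tibble.
#' @param samples Sample metadata with `condition_id`.
#' @param interaction_flags Tibble `sequence`, `associated` (logical);
#'   sequences absent from it count as unassociated.
#' @return Tibble of class `rsrna_spectrum`: `k`, `n_srnas`,
#'   `frac_associated`, `frac_unassociated`.
#' @export
recurrence_spectrum_report <- function(counts, samples, interaction_flags) {
  conds <- unique(samples$condition_id)
  sample_cols <- matrix_samples(counts)
  cond_of <- setNames(samples$condition_id, samples$sample_id)[sample_cols]
  mat <- as.matrix(counts[, sample_cols, drop = FALSE])
  pres <- sapply(conds, function(cc) {
    rowSums(mat[, cond_of == cc, drop = FALSE]) >= 1
  })
  if (nrow(counts) == 1) pres <- matrix(pres, nrow = 1)
  n_cond_present <- rowSums(pres)
  assoc <- setNames(rep(FALSE, nrow(counts)), counts$sequence)
  hitdx <- match(interaction_flags$sequence, counts$sequence)
  assoc[hitdx[!is.na(hitdx)]] <- interaction_flags$associated[!is.na(hitdx)]
  out <- purrr::map_dfr(seq_along(conds), function(k) {
    sel <- n_cond_present >= k
    tibble::tibble(
      k = k, n_srnas = sum(sel),
      frac_associated = if (sum(sel) > 0) mean(assoc[sel]) else NA_real_,
      frac_unassociated = if (sum(sel) > 0) mean(!assoc[sel]) else NA_real_)
  })
  class(out) <- c("rsrna_spectrum", class(out))
  out
}

#' Map dependence calls to a biogenesis label
#'
#' DGCR8-dependent candidates are Microprocessor products
#' (`drosha_dgcr8_dependent`); otherwise Dicer-dependent candidates are
#' `dicer_only`; anything else is `independent`.
#'
#' @param dicer_call,dgcr8_call Calls from [dependence_call()].
#' @return Character vector of labels.
#' @export
label_biogenesis <- function(dicer_call, dgcr8_call) {
  dplyr::case_when(
    dgcr8_call == "dependent" ~ "drosha_dgcr8_dependent",
    dicer_call == "dependent" ~ "dicer_only",
    TRUE ~ "independent")
}
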