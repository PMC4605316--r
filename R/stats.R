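# Differential-expression, correlation and enrichment statistics.

#' Pearson correlation with pairwise-complete missing-data handling
#'
#' Positions missing in either vector are dropped; the correlation is
#' computed on the complete pairs and its two-sided significance from the t
#' approximation `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom (p = 0 at r = +/-1).
#'
#' @param x,y Numeric vectors of equal length (NA allowed).
#' @param pairwise_complete Drop incomplete pairs (`TRUE`, default).
#' @return One-row tibble: `r`, `n_used`, `p_value`.
#' @export
pearson_correlation <- function(x, y, pairwise_complete = TRUE) {
  stopifnot(length(x) == length(y))
  if (pairwise_complete) {
    ok <- !(is.na(x) | is.na(y))
    x <- x[ok]; y <- y[ok]
  } else if (anyNA(x) || anyNA(y)) {
    stop("missing values present with pairwise_complete = FALSE")
  }
  n <- length(x)
  if (n < 3) stop("undefined correlation: fewer than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: zero variance")
  dx <- x - mean(x); dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(r = r, n_used = n, p_value = p)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom; thin wrapper over [stats::t.test()] returning a tidy row.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return One-row tibble: `t`, `df`, `p_value`.
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    # degenerate: t.test() refuses constant data; identical constants are a
    # perfectly uninformative comparison
    if (mean(group_a) == mean(group_b)) {
      return(tibble::tibble(t = 0, df = length(group_a) + length(group_b) - 2,
                            p_value = 1))
    }
    return(tibble::tibble(t = Inf * sign(mean(group_a) - mean(group_b)),
                          df = length(group_a) + length(group_b) - 2,
                          p_value = 0))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value)
}

#' Per-condition fold-change calls from an RPM matrix
#'
#' For every (sequence, condition): fold change = (mean tumor RPM +
#' pseudocount) / (mean normal RPM + pseudocount), a Welch t-test on the
#' per-sample RPM when both states have >= 2 samples, and a direction call.
#'
#' @param rpm Wide RPM tibble (`sequence` + sample columns).
#' @param samples Sample metadata with `sample_id`, `condition_id`, `state`
#'   (`"tumor"`/`"normal"`).
#' @param fold_change_min Fold-change threshold (either direction).
#' @param pseudocount Added to both means.
#' @return Tibble of differential calls: `sequence`, `condition_id`,
#'   `tumor_mean_rpm`, `normal_mean_rpm`, `fold_change`, `direction`,
#'   `de`, `t_statistic`, `p_value`. Conditions missing a state are skipped
#'   with a warning.
#' @export
fold_change_flags <- function(rpm, samples, fold_change_min = 2,
                              pseudocount = 0.5) {
  long <- tidyr::pivot_longer(rpm, -"sequence", names_to = "sample_id",
                              values_to = "rpm") |>
    dplyr::inner_join(samples, by = "sample_id")
  skip <- long |>
    dplyr::distinct(.data$condition_id, .data$state) |>
    dplyr::count(.data$condition_id) |>
    dplyr::filter(.data$n < 2)
  if (nrow(skip) > 0) {
    warning("condition(s) missing a state, skipped: ",
            paste(skip$condition_id, collapse = ", "))
    long <- dplyr::filter(long, !.data$condition_id %in% skip$condition_id)
  }
  calls <- long |>
    dplyr::group_by(.data$sequence, .data$condition_id) |>
    dplyr::summarise(
      tumor_mean_rpm = mean(.data$rpm[.data$state == "tumor"]),
      normal_mean_rpm = mean(.data$rpm[.data$state == "normal"]),
      t_statistic = if (sum(.data$state == "tumor") >= 2 &&
                        sum(.data$state == "normal") >= 2) {
        welch_ttest(.data$rpm[.data$state == "tumor"],
                    .data$rpm[.data$state == "normal"])$t
      } else NA_real_,
      p_value = if (sum(.data$state == "tumor") >= 2 &&
                    sum(.data$state == "normal") >= 2) {
        welch_ttest(.data$rpm[.data$state == "tumor"],
                    .data$rpm[.data$state == "normal"])$p_value
      } else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(
      fold_change = (.data$tumor_mean_rpm + pseudocount) /
        (.data$normal_mean_rpm + pseudocount),
      de = .data$fold_change >= fold_change_min |
        .data$fold_change <= 1 / fold_change_min,
      direction = dplyr::case_when(
        .data$fold_change >= fold_change_min ~ "up_in_tumor",
        .data$fold_change <= 1 / fold_change_min ~ "up_in_normal",
        TRUE ~ "unchanged"))
  dplyr::select(calls, "sequence", "condition_id", "tumor_mean_rpm",
                "normal_mean_rpm", "fold_change", "direction", "de",
                "t_statistic", "p_value")
}

#' Per-sequence differential-expression summary
#'
#' Summarizes [fold_change_flags()] output: a sequence is differentially
#' expressed iff its fold change crosses the threshold in at least one
#' condition; the direction summary tallies conditions up in tumor, up in
#' normal, or both.
#'
#' @param calls Output of [fold_change_flags()].
#' @return Tibble: `sequence`, `de`, `n_up_in_tumor`, `n_up_in_normal`,
#'   `direction_summary` (`up_in_tumor` / `up_in_normal` / `both` /
#'   `unchanged`).
#' @export
de_flags <- function(calls) {
  calls |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      de = any(.data$de),
      n_up_in_tumor = sum(.data$direction == "up_in_tumor"),
      n_up_in_normal = sum(.data$direction == "up_in_normal"),
      .groups = "drop") |>
    dplyr::mutate(direction_summary = dplyr::case_when(
      .data$n_up_in_tumor > 0 & .data$n_up_in_normal > 0 ~ "both",
      .data$n_up_in_tumor > 0 ~ "up_in_tumor",
      .data$n_up_in_normal > 0 ~ "up_in_normal",
      TRUE ~ "unchanged"))
}

#' Screen sRNA:gene pairs for expression anti-correlation
#'
#' For each candidate pair, computes the pairwise-complete Pearson
#' correlation between the sRNA's RPM and the gene's abundance over shared
#' samples. A pair passes iff `r <= pcc_max` and `p <= p_max`. Works
#' identically for RNA-seq RPKM, microarray, and protein matrices.
#'
#' @param srna_rpm Wide RPM tibble (`sequence` + sample columns).
#' @param expression Wide abundance tibble (`gene_id` + sample columns; NA
#'   allowed).
#' @param pairs Tibble of candidate pairs: `sequence`, `gene_id`.
#' @param pcc_max Correlation threshold (negative).
#' @param p_max Significance threshold.
#' @return `pairs` with `r`, `n_used`, `p_value`, `pass` (pairs with fewer
#'   than 3 complete observations get NA and `pass = FALSE`).
#' @export
anticorrelation_screen <- function(srna_rpm, expression, pairs,
                                   pcc_max = -0.5, p_max = 0.05) {
  shared <- intersect(matrix_samples(srna_rpm), matrix_samples(expression, "gene_id"))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    xs <- srna_rpm[srna_rpm$sequence == pairs$sequence[i], shared]
    ys <- expression[expression$gene_id == pairs$gene_id[i], shared]
    if (nrow(xs) != 1 || nrow(ys) != 1) {
      return(tibble::tibble(r = NA_real_, n_used = NA_integer_,
                            p_value = NA_real_))
    }
    tryCatch(pearson_correlation(as.numeric(xs[1, ]), as.numeric(ys[1, ])),
             error = function(e) tibble::tibble(r = NA_real_,
                                                n_used = NA_integer_,
                                                p_value = NA_real_))
  })
  out <- dplyr::bind_cols(pairs, res)
  out$pass <- !is.na(out$r) & out$r <= pcc_max & out$p_value <= p_max
  out
}

#' Correlate qPCR Ct profiles of sRNA:gene pairs
#'
#' Applies [pearson_correlation()] with pairwise-complete handling to rows of
#' a Ct table. The reported `pcc` is rounded to 2 decimals (round-half-even,
#' R's default); full precision is kept in `r`.
#'
#' @param ct_table Tibble: column `id` plus one numeric column per cell line
#'   (NA allowed).
#' @param pairs Tibble with `srna` and `gene` naming rows of `ct_table`.
#' @return Tibble: `srna`, `gene`, `r`, `pcc` (2-decimal), `n_used`,
#'   `reason` (NA unless the correlation is undefined).
#' @export
ct_correlation_table <- function(ct_table, pairs) {
  cols <- setdiff(names(ct_table), "id")
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    x <- as.numeric(ct_table[ct_table$id == pairs$srna[i], cols])
    y <- as.numeric(ct_table[ct_table$id == pairs$gene[i], cols])
    res <- tryCatch(pearson_correlation(x, y), error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(srna = pairs$srna[i], gene = pairs$gene[i],
                     r = NA_real_, pcc = NA_real_, n_used = NA_integer_,
                     reason = "fewer than 3 complete pairs or zero variance")
    } else {
      tibble::tibble(srna = pairs$srna[i], gene = pairs$gene[i],
                     r = res$r, pcc = round(res$r, 2), n_used = res$n_used,
                     reason = NA_character_)
    }
  })
}

#' Hypergeometric enrichment with Bonferroni correction
#'
#' Upper-tail hypergeometric test per category: `p_raw = P(X >= overlap)`
#' with population `|universe|`, successes `|category|`, draws
#' `|target_set|`; Bonferroni over the number of categories tested.
#'
#' @param target_set Character vector of genes of interest (subset of
#'   `universe`).
#' @param universe Character vector of all genes.
#' @param category_map Tibble: `gene_id`, `category`.
#' @return Tibble per category: `category`, `category_size`, `overlap`,
#'   `p_raw`, `p_bonferroni`.
#' @export
hypergeometric_enrichment <- function(target_set, universe, category_map) {
  if (length(universe) == 0) stop("empty universe")
  stopifnot(all(target_set %in% universe))
  category_map <- dplyr::filter(category_map, .data$gene_id %in% universe)
  cats <- sort(unique(category_map$category))
  n_univ <- length(unique(universe))
  n_draw <- length(unique(target_set))
  res <- purrr::map_dfr(cats, function(cc) {
    members <- unique(category_map$gene_id[category_map$category == cc])
    k <- length(intersect(members, target_set))
    p <- phyper(k - 1, length(members), n_univ - length(members), n_draw,
                lower.tail = FALSE)
    tibble::tibble(category = cc, category_size = length(members),
                   overlap = k, p_raw = p)
  })
  res$p_bonferroni <- pmin(1, res$p_raw * length(cats))
  res
}
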