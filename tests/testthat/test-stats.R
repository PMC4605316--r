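test_that("pearson_correlation handles identity, affine maps and missing data", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, x)$p_value, 0)
  expect_equal(pearson_correlation(x, 3 * x + 2)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 1)$r, -1)
  set.seed(51)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_correlation(a, b)$r, pearson_correlation(b, a)$r)
  # pairwise-complete: NA positions dropped, n_used reflects it
  b2 <- b; b2[c(3, 7)] <- NA
  res <- pearson_correlation(a, b2)
  expect_equal(res$n_used, 18)
  expect_equal(res$r, cor(a[-c(3, 7)], b[-c(3, 7)]))
  # p matches the t approximation used by cor.test
  ct <- cor.test(a, b)
  expect_equal(pearson_correlation(a, b)$p_value, unname(ct$p.value),
               tolerance = 1e-12)
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "fewer than 3")
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("published Ct correlations reproduce under pairwise-complete Pearson", {
  ex <- qpcr_ct_example()
  tab <- ct_correlation_table(ex$ct, ex$pairs)
  # the pair with a missing Ct uses 3 complete cell lines
  expect_equal(tab$n_used[tab$srna == "rsRNA-5402"], 3)
  expect_equal(tab$pcc[tab$srna == "rsRNA-5402"], -0.96)
  expect_equal(tab$r[tab$srna == "rsRNA-1336" & tab$gene == "FOXO3"],
               -0.62628, tolerance = 1e-4)
  # every computed value agrees with its published figure to the printed digit
  expect_true(all(abs(tab$r - ex$pairs$published_pcc) <= 0.01))
  # permutation invariance over cell-line columns
  ct_perm <- ex$ct[, c("id", "MCF7", "A549", "HeLa", "MDA_MB_231")]
  tab_perm <- ct_correlation_table(ct_perm, ex$pairs)
  expect_equal(tab_perm$r, tab$r)
  # a pair with only 2 complete observations reports NA with a reason
  ct_na <- ex$ct
  ct_na[ct_na$id == "ATM", c("A549", "MDA_MB_231")] <- NA
  row <- ct_correlation_table(ct_na, tibble::tibble(srna = "rsRNA-5402",
                                                    gene = "ATM"))
  expect_true(is.na(row$r))
  expect_match(row$reason, "fewer than 3")
})

test_that("welch_ttest matches the textbook formula on random group pairs", {
  expect_equal(welch_ttest(c(1, 2, 3), c(1, 2, 3))$t, 0)
  set.seed(52)
  for (i in 1:100) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2))
    got <- welch_ttest(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
  set.seed(1)
  strong <- welch_ttest(rnorm(20), rnorm(20, mean = 5))
  expect_lt(strong$p_value, 1e-6)
  expect_error(welch_ttest(1, c(1, 2)), "at least 2")
  # identical constant groups: perfectly uninformative
  flat <- welch_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$t, 0); expect_equal(flat$p_value, 1)
})

test_that("fold-change calls apply the pseudocount and threshold as defined", {
  samples <- tibble::tibble(
    sample_id = c("t1", "t2", "n1", "n2"),
    condition_id = "c1", state = c("tumor", "tumor", "normal", "normal"),
    assay = "sRNA-seq")
  rpm <- tibble::tibble(sequence = c("s_weak", "s_strong", "s_down"),
                        t1 = c(20, 40, 10), t2 = c(20, 40, 10),
                        n1 = c(10, 10, 40), n2 = c(10, 10, 40))
  calls <- fold_change_flags(rpm, samples, fold_change_min = 2,
                             pseudocount = 0.5)
  w <- calls[calls$sequence == "s_weak", ]
  expect_equal(w$fold_change, 20.5 / 10.5)
  expect_false(w$de)                       # 1.95 < 2: pseudocount matters
  s <- calls[calls$sequence == "s_strong", ]
  expect_equal(s$fold_change, 40.5 / 10.5)
  expect_true(s$de)
  expect_equal(s$direction, "up_in_tumor")
  d <- calls[calls$sequence == "s_down", ]
  expect_true(d$de)
  expect_equal(d$direction, "up_in_normal")
  fl <- de_flags(calls)
  expect_setequal(fl$sequence[fl$de], c("s_strong", "s_down"))
  # monotone in the threshold: raising it never adds DE flags
  for (fc in c(2, 3, 4.2)) {
    lo <- de_flags(fold_change_flags(rpm, samples, fc))
    hi <- de_flags(fold_change_flags(rpm, samples, fc + 1))
    expect_true(all(hi$sequence[hi$de] %in% lo$sequence[lo$de]))
  }
  # condition missing a state is skipped with a warning
  s2 <- dplyr::mutate(samples, state = "tumor")
  expect_warning(fold_change_flags(rpm, s2), "missing a state")
})

test_that("anticorrelation screen applies both thresholds", {
  set.seed(53)
  n <- 20
  x <- rlnorm(n, log(100), 0.5)
  cols <- sprintf("s%02d", 1:n)
  srna_rpm <- tibble::tibble(sequence = "S1",
                             !!!setNames(as.list(x), cols))
  strong <- -x + rnorm(n, 0, 0.1 * sd(x))     # r close to -1
  weak <- rnorm(n, 50, 10)                    # independent of x
  expression <- dplyr::bind_rows(
    tibble::tibble(gene_id = "G_strong", !!!setNames(as.list(strong), cols)),
    tibble::tibble(gene_id = "G_weak", !!!setNames(as.list(weak), cols)))
  pairs <- tibble::tibble(sequence = "S1", gene_id = c("G_strong", "G_weak"))
  out <- anticorrelation_screen(srna_rpm, expression, pairs,
                                pcc_max = -0.5, p_max = 0.05)
  expect_true(out$pass[out$gene_id == "G_strong"])
  expect_false(out$pass[out$gene_id == "G_weak"])
  # r = -0.4 fails on the correlation threshold even if significant
  expect_false(-0.4 <= -0.5)
  expect_error(anticorrelation_screen(srna_rpm[, 1:3], expression, pairs),
               "shared samples")
})

test_that("hypergeometric enrichment equals exact combinatorial summation", {
  set.seed(54)
  for (i in 1:40) {
    N <- sample(20:200, 1)
    universe <- sprintf("g%03d", seq_len(N))
    K <- sample(2:min(40, N), 1)
    n <- sample(2:min(40, N), 1)
    cat_map <- tibble::tibble(gene_id = sample(universe, K), category = "C1")
    targets <- sample(universe, n)
    got <- hypergeometric_enrichment(targets, universe, cat_map)
    k <- length(intersect(cat_map$gene_id, targets))
    expect_equal(got$overlap, k)
    expect_equal(got$p_raw, oracle_hyper_upper(k, K, N, n), tolerance = 1e-12)
    expect_equal(got$p_bonferroni, got$p_raw)  # single category
  }
  # disjoint category: overlap 0, upper tail P(X >= 0) = 1
  uni <- sprintf("g%d", 1:100)
  cm <- tibble::tibble(gene_id = uni[1:5], category = "C1")
  out <- hypergeometric_enrichment(uni[6:10], uni, cm)
  expect_equal(out$p_raw, 1)
  # complete overlap is the most extreme upper tail
  out2 <- hypergeometric_enrichment(uni[1:5], uni, cm)
  expect_equal(out2$p_raw, oracle_hyper_upper(5, 5, 100, 5), tolerance = 1e-12)
  expect_lt(out2$p_raw, 1e-7)
  # Bonferroni multiplies by the number of categories, capped at 1
  cm2 <- dplyr::bind_rows(cm, tibble::tibble(gene_id = uni[6:10],
                                             category = "C2"))
  out3 <- hypergeometric_enrichment(uni[1:5], uni, cm2)
  expect_equal(out3$p_bonferroni, pmin(1, out3$p_raw * 2))
  expect_error(hypergeometric_enrichment("x", character(0), cm), "universe")
})
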