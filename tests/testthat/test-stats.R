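test_that("shuffle test: empirical p has the add-one floor and ceiling", {
  gen <- genome_def("chr1", 100000)
  # query sits inside the target; uniform placement almost never hits a
  # tiny target, so observed exceeds every null draw
  query <- tibble::tibble(chrom = "chr1", start = 5000, end = 5050)
  target <- tibble::tibble(chrom = "chr1", start = 5000, end = 5060)
  res <- shuffle_overlap_test(query, target, gen, n_perm = 9999, seed = 2)
  expect_equal(res$observed, 1)
  expect_equal(res$p_empirical, (1 + res$n_as_extreme) / 10000)
  expect_gte(res$p_empirical, 1e-4)

  # target covers the whole chromosome: every shuffle overlaps, p = 1
  full <- tibble::tibble(chrom = "chr1", start = 0, end = 100000)
  res_full <- shuffle_overlap_test(query, full, gen, n_perm = 99, seed = 3)
  expect_equal(res_full$p_empirical, 1)

  expect_error(shuffle_overlap_test(
    tibble::tibble(chrom = "chr1", start = 0, end = 2e5), full,
    gen, n_perm = 9, seed = 1), "exceeds")
})

test_that("shuffle test is reproducible bit-for-bit under a fixed seed", {
  set.seed(99)
  gen <- genome_def(c("chr1", "chr2"), c(50000, 80000))
  query <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                          start = sample(0:40000, 20))
  query$end <- query$start + sample(100:2000, 20, TRUE)
  target <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                           start = sample(0:40000, 10))
  target$end <- target$start + 1500
  r1 <- shuffle_overlap_test(query, target, gen, n_perm = 199, seed = 7)
  r2 <- shuffle_overlap_test(query, target, gen, n_perm = 199, seed = 7)
  expect_identical(r1$null_draws, r2$null_draws)
  expect_identical(tidy(r1), tidy(r2))
  r3 <- shuffle_overlap_test(query, target, gen, n_perm = 199, seed = 8)
  expect_false(identical(r1$null_draws, r3$null_draws))
  # direction flip complements the extreme count
  rl <- shuffle_overlap_test(query, target, gen, n_perm = 199, seed = 7,
                             direction = "less")
  expect_identical(rl$null_draws, r1$null_draws)
})

test_that("gene-set permutation: degenerate and error cases", {
  gt <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                       cdna_length = sort(sample(200:5000, 200)),
                       indicator = TRUE)
  # indicator true for all genes: observed = |set|, p = 1
  res <- geneset_permutation_enrich(gt, gt$gene_id[1:30], n_perm = 99,
                                    seed = 1)
  expect_equal(res$observed, 30)
  expect_equal(res$p_empirical, 1)

  expect_error(geneset_permutation_enrich(gt, c("nope"), n_perm = 9),
               "absent")
  expect_error(geneset_permutation_enrich(gt, gt$gene_id[1:5],
                                          covariate = "missing_col",
                                          n_perm = 9), "covariate")
})

test_that("chi-squared equals the closed form; worked tables check out", {
  expect_equal(contingency_test(10, 10, 10, 10)$chi2, 0)
  expect_equal(contingency_test(10, 10, 10, 10)$odds_ratio, 1)
  expect_equal(contingency_test(2, 1, 1, 2)$odds_ratio, 4)

  # the ASD-gene style table: 96/102 vs 11,420/17,382 qualifying
  big <- contingency_test(96, 6, 11420, 5962)
  ref <- suppressWarnings(
    stats::chisq.test(rbind(c(96, 6), c(11420, 5962)), correct = FALSE))
  expect_equal(big$chi2, unname(ref$statistic))
  expect_equal(big$p_chi2, ref$p.value)
  expect_gt(big$chi2, 30)

  set.seed(5)
  for (i in 1:200) {
    cl <- rpois(4, sample(c(3, 20, 200), 1)) + 1
    ct <- contingency_test(cl[1], cl[2], cl[3], cl[4])
    ref <- suppressWarnings(stats::chisq.test(matrix(cl, 2, byrow = TRUE),
                                              correct = FALSE))
    expect_equal(ct$chi2, unname(ref$statistic))
  }
})

test_that("Fisher p equals exhaustive hypergeometric enumeration", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    a <- sample(0:min(n, 12), 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    expect_equal(contingency_test(a, b, c, d)$p_fisher,
                 oracle_fisher2(a, b, c, d), tolerance = 1e-12)
  }
})

test_that("degenerate tables flag the adjusted odds ratio", {
  ct <- contingency_test(5, 0, 3, 7)
  expect_true(ct$or_adjusted)
  expect_equal(ct$odds_ratio, (5.5 * 7.5) / (0.5 * 3.5))
  zero_margin <- contingency_test(0, 0, 3, 7)
  expect_true(is.na(zero_margin$chi2))
})

test_that("gene-set Fisher enrichment applies the chosen correction", {
  universe <- sprintf("g%03d", 1:300)
  target <- universe[1:40]
  sets <- list(hit = universe[1:40], miss = universe[250:300],
               part = universe[30:60])
  res <- geneset_fisher_enrich(target, sets, universe)
  expect_equal(res$a[res$set == "hit"], 40)
  expect_lt(res$p_fisher[res$set == "hit"], 1e-10)
  expect_true(all(res$p_adj >= res$p_fisher))
  expect_true(all(res$p_adj <= pmin(1, 3 * res$p_fisher) + 1e-12))
  # depletion direction: fewer shared genes than expected
  expect_lt(res$odds_ratio[res$set == "miss"], 1)
  bh <- geneset_fisher_enrich(target, sets, universe, correction = "BH")
  expect_true(all(bh$p_adj <= res$p_adj + 1e-12))
  expect_error(geneset_fisher_enrich(target, sets, character()), "empty")
})

test_that("DEX filtering is inclusive at both thresholds", {
  dge <- tibble::tibble(
    gene_id = c("at_fc", "at_p", "weak_fc", "strong_dn", "null"),
    log2fc = c(1, 2.5, 0.9, -1.3, 0.1),
    padj = c(0.01, 0.05, 0.01, 0.001, 0.8))
  res <- dex_filter(dge)
  expect_setequal(res$up, c("at_fc", "at_p"))
  expect_equal(res$down, "strong_dn")
  expect_length(intersect(res$up, res$down), 0)
  expect_error(dex_filter(dge[, 1:2]), "lacks")
})

test_that("planted DEX genes are recovered exactly from the generator", {
  b <- generate_dataset(synthetic_config(seed = 21, n_genes = 300,
                                         n_chroms = 3, chrom_length = 6e5,
                                         geneset_size = 50,
                                         dge_n_up = 7, dge_n_down = 5))
  res <- dex_filter(b$dge_table)
  expect_setequal(res$up, b$truth$dex_up)
  expect_setequal(res$down, b$truth$dex_down)
})

test_that("delta-delta-Ct closed forms", {
  expect_equal(ddct(20, 18, 20, 18)$rel_expression, 1)
  expect_equal(ddct(19, 18, 20, 18)$delta_delta_ct, -1)
  expect_equal(ddct(19, 18, 20, 18)$rel_expression, 2)
  # ddCt = log2(10) is a ten-fold decrease
  res <- ddct(20 + log2(10), 18, 20, 18)
  expect_equal(res$rel_expression, 0.1)
  # several housekeeping genes combine by mean Ct
  expect_equal(ddct(20, c(17, 19), 20, c(18, 18))$rel_expression, 1)
  expect_error(ddct(NA, 18, 20, 18), "finite")
})

test_that("tissue enrichment filters small tissues and flags zero cells", {
  set.seed(31)
  n_el <- 160
  elements <- tibble::tibble(
    element_id = sprintf("el%03d", 1:n_el), chrom = "chr1",
    start = seq(0, by = 5000, length.out = n_el))
  elements$end <- elements$start + 1000
  # loci overlap the first half of the elements
  loci <- tibble::tibble(chrom = "chr1", start = elements$start[1:80] + 100,
                         end = elements$start[1:80] + 400)
  # tissue A: positives strongly enriched among overlapped elements;
  # tissue B: only 49 positives -> excluded
  pos_a <- c(rbinom(80, 1, 0.75), rbinom(80, 1, 0.25)) == 1
  pos_b <- seq_len(n_el) <= 49
  vista <- dplyr::bind_rows(
    dplyr::mutate(elements, tissue = "forebrain", positive = pos_a),
    dplyr::mutate(elements, tissue = "limb", positive = pos_b))
  res <- vista_tissue_enrichment(vista, loci, min_positive_per_tissue = 50)
  expect_equal(res$tissue, "forebrain")
  expect_gt(res$odds_ratio, 1)
  expect_equal(res$p_fisher,
               oracle_fisher2(res$a, res$b, res$c, res$d))
  expect_error(vista_tissue_enrichment(vista, loci,
                                       min_positive_per_tissue = 200),
               "no tissue")
  # all elements overlapping -> zero cells, adjusted OR flagged
  all_loci <- tibble::tibble(chrom = "chr1", start = 0,
                             end = max(elements$end))
  res2 <- vista_tissue_enrichment(vista, all_loci)
  expect_true(all(res2$or_adjusted))
})

test_that("expression stratification summarises and degenerates sanely", {
  profile <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                            proximal_tr_count = 0L,
                            proximal_atac = FALSE, distal_link = FALSE)
  expr <- tibble::tibble(gene_id = profile$gene_id,
                         log2_tpm1 = c(rep(0, 10), runif(10, 0, 0.5)))
  res <- expression_stratify(profile, expr)
  one <- dplyr::filter(tidy(res), n > 0)
  expect_equal(nrow(one), 1)
  expect_equal(one$median, median(expr$log2_tpm1))
  # all below threshold: robust fraction 0, logistic fit skipped
  expect_equal(one$frac_robust, 0)
  expect_null(res$model)
  expect_error(expression_stratify(profile,
                                   dplyr::mutate(expr, log2_tpm1 = -1)),
               ">= 0")
})
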