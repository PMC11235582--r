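mk_peak <- function(chrom, start, end, assay, class = "distal") {
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = paste0(assay, "_", start), strand = ".",
                 score_neglog10p = 1, assay = assay, class = class)
}

test_that("five coincident peaks plus ATAC give one 5TRa locus", {
  trs <- c("ARID1B", "BCL11A", "FOXP1", "TBR1", "TCF7L2")
  peaks <- dplyr::bind_rows(lapply(trs, function(a)
    mk_peak("chr1", 100, 200, a, "proximal")))
  atac <- tibble::tibble(chrom = "chr1", start = 150, end = 160)
  loci <- merge_loci(peaks, atac)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$tr_count, 5L)
  expect_equal(loci$membership[[1]], sort(trs))
  expect_true(loci$atac)
  expect_equal(loci$class, "proximal")
})

test_that("overlap chains merge transitively; bookends do not merge", {
  peaks <- dplyr::bind_rows(mk_peak("chr1", 0, 10, "A"),
                            mk_peak("chr1", 5, 15, "B"),
                            mk_peak("chr1", 14, 20, "C"))
  loci <- merge_loci(peaks)
  expect_equal(nrow(loci), 1)
  expect_equal(c(loci$start, loci$end), c(0, 20))
  expect_equal(loci$membership[[1]], c("A", "B", "C"))

  booked <- dplyr::bind_rows(mk_peak("chr1", 0, 10, "A"),
                             mk_peak("chr1", 10, 20, "B"))
  expect_equal(nrow(merge_loci(booked)), 2)

  singles <- dplyr::bind_rows(mk_peak("chr1", 0, 10, "A"),
                              mk_peak("chr1", 100, 110, "B"),
                              mk_peak("chr2", 0, 10, "C"))
  ls <- merge_loci(singles)
  expect_equal(nrow(ls), 3)
  expect_true(all(ls$tr_count == 1L))
})

test_that("a merged locus containing any proximal peak is proximal", {
  peaks <- dplyr::bind_rows(mk_peak("chr1", 0, 100, "A", "proximal"),
                            mk_peak("chr1", 50, 200, "B", "distal"))
  expect_equal(merge_loci(peaks)$class, "proximal")
})

test_that("locus merging equals per-base connected components", {
  for (seed in 1:25) {
    fx <- random_small_genome(seed)
    peaks <- fx$peaks
    peaks$class <- "distal"
    loci <- merge_loci(peaks)
    orc <- oracle_merge(peaks, fx$L)
    expect_equal(nrow(loci), length(orc))
    loci <- dplyr::arrange(loci, start)
    for (k in seq_along(orc)) {
      expect_equal(loci$start[k], orc[[k]]$start)
      expect_equal(loci$end[k], orc[[k]]$end)
      expect_equal(loci$membership[[k]], orc[[k]]$membership)
    }
    # membership subsets partition the loci
    mc <- membership_counts(loci, by_class = FALSE)
    expect_equal(sum(mc$subsets$n), nrow(loci))
  }
})

test_that("membership counts report per-subset and per-count percentages", {
  loci <- tibble::tibble(
    chrom = "chr1",
    start = seq(0, by = 1000, length.out = 6),
    end = seq(100, by = 1000, length.out = 6),
    class = "proximal",
    membership = list(c("A", "B"), c("A", "B"), "A", "A", "B", c("A", "B")),
    tr_count = c(2L, 2L, 1L, 1L, 1L, 2L),
    atac = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  mc <- membership_counts(loci)
  two <- dplyr::filter(mc$by_tr_count, tr_count == 2)
  expect_equal(two$n, 3L)
  expect_equal(two$n_atac, 2L)
  expect_equal(two$pct_atac, 100 * 2 / 3)
  expect_equal(sum(mc$subsets$n), 6L)
  empty <- membership_counts(loci[0, ])
  expect_equal(nrow(empty$subsets), 0)
})

test_that("overlap fractions match hand counts and the oracle", {
  q <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  t1 <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
  of <- overlap_fractions(q, t1)
  expect_equal(of$peak_fraction, 100)
  expect_equal(of$nucleotide_fraction, 50)

  expect_equal(unlist(overlap_fractions(q, q)[c("peak_fraction",
                                                "nucleotide_fraction")]),
               c(peak_fraction = 100, nucleotide_fraction = 100))
  disj <- tibble::tibble(chrom = "chr1", start = 500, end = 600)
  expect_equal(overlap_fractions(q, disj)$peak_fraction, 0)
  expect_equal(overlap_fractions(q, disj)$nucleotide_fraction, 0)
  expect_error(overlap_fractions(q[0, ], t1), "empty")

  # invariant to splitting the target into adjacent pieces
  t_split <- tibble::tibble(chrom = "chr1", start = c(50, 80, 120),
                            end = c(80, 120, 150))
  expect_equal(overlap_fractions(q, t_split), of)

  for (seed in 1:10) {
    fx <- random_small_genome(seed)
    q2 <- fx$peaks[fx$peaks$assay == "A", ]
    t2 <- fx$peaks[fx$peaks$assay != "A", ]
    if (nrow(q2) == 0 || nrow(t2) == 0) next
    got <- overlap_fractions(q2, t2)
    orc <- oracle_overlap_fractions(q2, t2, fx$L)
    expect_equal(got$peak_fraction, unname(orc["peak"]))
    expect_equal(got$nucleotide_fraction, unname(orc["nucleotide"]))
  }
})

test_that("conservation maxima use overlapping track intervals, 0 otherwise", {
  loci <- tibble::tibble(chrom = "chr1", start = c(0, 1000),
                         end = c(100, 1100))
  track <- tibble::tibble(chrom = "chr1", start = c(0, 50),
                          end = c(50, 90), value = c(0.2, 0.9))
  cs <- conservation_summary(loci, track, 0.5)
  expect_equal(cs$per_locus$max_score, c(0.9, 0))
  expect_equal(cs$summary$fraction_above, 50)
  expect_error(conservation_summary(loci, track, 1.5), "outside")

  for (seed in 1:10) {
    fx <- random_small_genome(seed)
    loci2 <- merge_loci(dplyr::mutate(fx$peaks, class = "distal"))
    starts <- seq(0, fx$L - 200, by = 200)
    keep <- sort(sample(seq_along(starts), 20))
    track2 <- tibble::tibble(chrom = "chrT", start = starts[keep],
                             end = starts[keep] + sample(50:200, 20, TRUE),
                             value = round(runif(20), 3))
    got <- conservation_summary(loci2, track2)$per_locus$max_score
    expect_equal(got, oracle_max_scores(loci2, track2, fx$L))
  }
})

test_that("distal window linking is monotone and respects the filters", {
  gen_genes <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(gene_id = sprintf("g%d", i), chrom = "chr1",
                   strand = "+", tss_list = list(i * 1000000),
                   cdna_length = 1000, biotype = "protein_coding")
  }))
  trio <- c("ARID1B", "BCL11A", "TBR1")
  loci <- tibble::tibble(
    chrom = "chr1",
    start = c(1 * 1000000 + 50000, 2 * 1000000 + 400000, 3 * 1000000 + 600000),
    end = c(1 * 1000000 + 51000, 2 * 1000000 + 401000, 3 * 1000000 + 601000),
    class = "distal",
    membership = list(trio, trio, trio),
    tr_count = 3L,
    atac = c(TRUE, TRUE, FALSE))
  res <- link_distal_to_genes(loci, gen_genes, link_config(),
                              gene_set = gen_genes$gene_id)
  # 100 kb: only g1; 500 kb: g1 and g2; the ATAC-less locus never counts
  expect_equal(res$summary$n_set_linked, c(1L, 2L))
  expect_equal(res$summary$pct_set_linked, c(20, 40))
  # monotone non-decreasing in window size
  expect_true(all(diff(res$summary$n_linked) >= 0))

  # window 0 links only loci overlapping a TSS
  cfg0 <- link_config(windows_bp = 0, required_assays = NULL,
                      min_tr_count = 3)
  ov <- tibble::tibble(chrom = "chr1", start = 1000000 - 10,
                       end = 1000000 + 10, class = "distal",
                       membership = list(trio), tr_count = 3L, atac = TRUE)
  res0 <- link_distal_to_genes(dplyr::bind_rows(ov, loci), gen_genes, cfg0)
  expect_equal(res0$linked$gene_id, "g1")
  expect_error(link_distal_to_genes(loci, gen_genes, link_config(),
                                    gene_set = character()), "empty")
})

test_that("cross-dataset matching reports the overlapped fraction", {
  a <- tibble::tibble(chrom = "chr1", start = c(0, 100, 200),
                      end = c(50, 150, 250))
  attr(a, "genome") <- "hg38"
  b <- a
  expect_equal(cross_dataset_locus_match(a, b)$pct_matched, 100)
  c_tbl <- tibble::tibble(chrom = "chr1", start = 1000, end = 1100)
  attr(c_tbl, "genome") <- "hg38"
  expect_equal(cross_dataset_locus_match(a, c_tbl)$pct_matched, 0)
  d <- a; attr(d, "genome") <- "mm10"
  expect_error(cross_dataset_locus_match(a, d), "coordinate spaces")

  for (seed in 1:10) {
    fx <- random_small_genome(seed)
    x <- fx$peaks[fx$peaks$assay == "A", c("chrom", "start", "end")]
    y <- fx$peaks[fx$peaks$assay == "B", c("chrom", "start", "end")]
    if (nrow(x) == 0 || nrow(y) == 0) next
    got <- cross_dataset_locus_match(x, y)$pct_matched
    expect_equal(got, oracle_overlap_fractions(x, y, fx$L)[["peak"]])
  }
})
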