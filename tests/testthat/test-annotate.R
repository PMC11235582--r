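mk_gene <- function(gene_id, strand, tss, chrom = "chr1",
                    cdna_length = 1000) {
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 tss_list = list(tss), cdna_length = cdna_length,
                 biotype = "protein_coding")
}

test_that("promoter windows are strand-aware, merged and clipped", {
  gen <- genome_def("chr1", 1e6)
  p1 <- build_promoters(mk_gene("g1", "+", 10000), 2000, gen)
  expect_equal(p1$start, 8000)
  expect_equal(p1$end, 10000)

  # two + strand TSSs 500 bp apart: union [8000,10000) u [8500,10500)
  # merges to one window of 2500 bp
  p2 <- build_promoters(mk_gene("g1", "+", c(10000, 10500)), 2000, gen)
  expect_equal(nrow(p2), 1)
  expect_equal(c(p2$start, p2$end), c(8000, 10500))
  expect_equal(sum(p2$end - p2$start), 2500)

  # - strand: upstream toward larger coordinates, TSS base excluded
  p3 <- build_promoters(mk_gene("g2", "-", 10000), 2000, gen)
  expect_equal(c(p3$start, p3$end), c(10001, 12001))

  # clipping at the chromosome edge
  p4 <- build_promoters(mk_gene("g3", "+", 500), 2000, gen)
  expect_equal(c(p4$start, p4$end), c(0, 500))

  expect_error(build_promoters(mk_gene("g4", "+", 2e6), 2000, gen),
               "outside")
})

test_that("promoter windows never include the TSS base or transcribed side", {
  gen <- genome_def("chr1", 50000)
  for (strand in c("+", "-")) {
    for (tss in c(5000, 20000)) {
      pr <- build_promoters(mk_gene("g", strand, tss), 2000, gen)
      bases <- unlist(Map(seq, pr$start, pr$end - 1))
      expect_false(tss %in% bases)
      downstream <- if (strand == "+") tss + 1 else tss - 1
      expect_false(downstream %in% bases)
      expect_lte(length(bases), 2000)
    }
  }
})

test_that("peaks classify proximal on >=1 bp overlap, else nearest TSS", {
  gen <- genome_def("chr1", 1e6)
  genes <- dplyr::bind_rows(mk_gene("g1", "+", 10000),
                            mk_gene("g2", "+", 25000))
  prom <- build_promoters(genes, 2000, gen)
  peaks <- tibble::tibble(
    chrom = "chr1",
    start = c(9990, 20000),
    end = c(10050, 20100),
    name = c("pk1", "pk2"), strand = ".",
    score_neglog10p = c(5, 5), assay = "TR")
  ann <- classify_peaks(peaks, prom, genes)
  expect_equal(ann$class, c("proximal", "distal"))
  expect_equal(ann$proximal_genes[[1]], "g1")
  # distance from the end-exclusive peak edge (base 20099) to TSS 25000
  expect_equal(ann$distal_gene[2], "g2")
  expect_equal(ann$distance_bp[2], 4901)
})

test_that("equidistant TSSs resolve to the lexicographically first gene", {
  gen <- genome_def("chr1", 1e6)
  genes <- dplyr::bind_rows(mk_gene("gB", "+", 94990),
                            mk_gene("gA", "+", 105100))
  prom <- build_promoters(genes, 2000, gen)
  # peak [99990,100101): edges 99990 and 100100; both TSSs 5000 bp away
  pk <- tibble::tibble(chrom = "chr1", start = 99990, end = 100101,
                       name = "p", strand = ".", score_neglog10p = 1,
                       assay = "TR")
  ann <- classify_peaks(pk, prom, genes)
  expect_equal(ann$class, "distal")
  expect_equal(ann$distal_gene, "gA")
})

test_that("a peak on a chromosome without genes is distal and unassigned", {
  gen <- genome_def(c("chr1", "chrUn"), c(1e6, 1e6))
  genes <- mk_gene("g1", "+", 10000)
  prom <- build_promoters(genes, 2000, gen)
  pk <- tibble::tibble(chrom = "chrUn", start = 100, end = 200,
                       name = "p", strand = ".", score_neglog10p = 1,
                       assay = "TR")
  ann <- classify_peaks(pk, prom, genes)
  expect_equal(ann$class, "distal")
  expect_true(is.na(ann$distal_gene))
})

test_that("classification partitions peaks and matches the per-base oracle", {
  for (seed in 1:25) {
    fx <- random_small_genome(seed)
    prom <- build_promoters(fx$genes, fx$window, fx$genome)
    ann <- classify_peaks(fx$peaks, prom, fx$genes)
    expect_true(all(ann$class %in% c("proximal", "distal")))
    expect_equal(sum(ann$class == "proximal") + sum(ann$class == "distal"),
                 nrow(fx$peaks))
    # proximal <=> proximal_genes non-empty; distal <=> gene + distance set
    expect_equal(lengths(ann$proximal_genes) > 0, ann$class == "proximal")
    expect_equal(!is.na(ann$distal_gene), ann$class == "distal")
    orc <- oracle_classify(fx$peaks, fx$genes, fx$window, fx$L)
    for (j in seq_len(nrow(fx$peaks))) {
      expect_equal(ann$class[j], orc[[j]]$class)
      expect_equal(ann$proximal_genes[[j]], orc[[j]]$proximal_genes)
      if (ann$class[j] == "distal") {
        expect_equal(ann$distance_bp[j], orc[[j]]$distance)
        expect_equal(ann$distal_gene[j], orc[[j]]$distal_gene)
      }
    }
  }
})

test_that("proximal signature summary reports count and percentage", {
  gen <- genome_def("chr1", 1e7)
  genes <- dplyr::bind_rows(lapply(1:10, function(i) {
    mk_gene(sprintf("g%02d", i), "+", i * 100000)
  }))
  prom <- build_promoters(genes, 2000, gen)
  # 5TRa loci at the promoters of the first 7 genes only
  loci <- tibble::tibble(
    chrom = "chr1",
    start = (1:7) * 100000 - 1000, end = (1:7) * 100000 - 400,
    class = "proximal",
    membership = rep(list(c("A", "B", "C", "D", "E")), 7),
    tr_count = 5L, atac = TRUE)
  res <- genes_with_proximal_signature(loci, prom, 5, TRUE,
                                       gene_set = genes$gene_id)
  expect_equal(res$summary$n_linked, 7)
  expect_equal(res$summary$pct_linked, 70)
  # relaxing the filters admits nothing new here
  res0 <- genes_with_proximal_signature(loci, prom, 0, FALSE)
  expect_equal(res0$genes, sprintf("g%02d", 1:7))
  expect_error(genes_with_proximal_signature(loci, prom, 5, TRUE,
                                             gene_set = character()),
               "empty")
})
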