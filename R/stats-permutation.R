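# Permutation nulls. Both tests return a `perm_test` object with the
# observed statistic, the add-one empirical p, and a null summary.
#
# p_empirical = (1 + n_as_extreme) / (1 + n_perm), so p is never 0 and its
# floor is 1/(n_perm + 1).

#' @noRd
new_perm_test <- function(observed, null_draws, n_perm, seed, direction,
                          statistic) {
  n_as_extreme <- switch(direction,
    greater = sum(null_draws >= observed),
    less = sum(null_draws <= observed),
    abort("direction must be 'greater' or 'less'"))
  structure(list(
    statistic = statistic,
    observed = observed,
    n_perm = n_perm,
    n_as_extreme = n_as_extreme,
    p_empirical = (1 + n_as_extreme) / (1 + n_perm),
    direction = direction,
    seed = seed,
    null_summary = tibble(mean = mean(null_draws), sd = stats::sd(null_draws),
                          min = min(null_draws), max = max(null_draws)),
    null_draws = null_draws
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s): observed %s = %.4g\n",
              x$direction, x$statistic, x$observed))
  cat(sprintf("  null mean %.4g (sd %.4g), %d permutations, seed %d\n",
              x$null_summary$mean, x$null_summary$sd, x$n_perm, x$seed))
  cat(sprintf("  empirical p = %.4g\n", x$p_empirical))
  invisible(x)
}

#' Length-preserving interval-shuffle overlap test
#'
#' Tests whether the observed number of query loci overlapping a target set
#' exceeds (or falls below) what uniform placement would give. The null
#' re-places every query locus uniformly at random on its own chromosome
#' with its length preserved, placements independent and overlaps among
#' shuffled loci allowed — i.e., a null that accounts for the number and
#' size of the query loci but not their positions.
#'
#' Under that null each locus overlaps the target independently with an
#' exactly computable probability (the fraction of valid start positions
#' that touch the target), so null draws are sampled as independent
#' Bernoulli indicators rather than by materialising coordinates; the null
#' distribution is identical.
#'
#' @param loci_query,loci_target interval tibbles.
#' @param genome [genome_def()] covering all query loci.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @param direction `"greater"` (enrichment, default) or `"less"`.
#' @return a `perm_test` object.
#' @export
shuffle_overlap_test <- function(loci_query, loci_target, genome,
                                 n_perm = 10000, seed = 1,
                                 direction = "greater") {
  validate_intervals(loci_query, "query loci")
  validate_intervals(loci_target, "target loci")
  check_genome_fit(loci_query, genome, "query loci")
  if (nrow(loci_query) == 0) abort("empty query")
  q_gr <- as_granges(loci_query |> select("chrom", "start", "end"))
  t_gr <- GenomicRanges::reduce(
    as_granges(loci_target |> select("chrom", "start", "end")),
    ignore.strand = TRUE)
  observed <- sum(GenomicRanges::countOverlaps(q_gr, t_gr,
                                               ignore.strand = TRUE) > 0)
  # exact per-locus overlap probability under uniform placement
  target_by_chrom <- split(granges_to_tbl(t_gr),
                           as.character(GenomicRanges::seqnames(t_gr)))
  p_hit <- map_dbl(seq_len(nrow(loci_query)), function(i) {
    chrom <- loci_query$chrom[i]
    len <- loci_query$end[i] - loci_query$start[i]
    chrom_len <- genome$length[match(chrom, genome$chrom)]
    if (len > chrom_len) abort("locus longer than its chromosome")
    n_starts <- chrom_len - len + 1
    tg <- target_by_chrom[[chrom]]
    if (is.null(tg) || nrow(tg) == 0) return(0)
    # start s overlaps [t1, t2) iff s in [t1 - len + 1, t2 - 1]
    lo <- pmax(tg$start - len + 1, 0)
    hi <- pmin(tg$end - 1, chrom_len - len)
    hit_ir <- IRanges::reduce(IRanges::IRanges(lo[lo <= hi] + 1L,
                                               hi[lo <= hi] + 1L))
    sum(IRanges::width(hit_ir)) / n_starts
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- matrix(stats::runif(n_perm * length(p_hit)), nrow = n_perm)
  null_draws <- as.integer(rowSums(sweep(draws, 2, p_hit, "<")))
  new_perm_test(observed, null_draws, n_perm, seed, direction,
                statistic = "n_query_overlapping")
}

#' Covariate-matched gene-set permutation enrichment
#'
#' Tests whether genes of a set carry a binary indicator (e.g., "has a
#' proximal five-TR + ATAC locus") more often than random gene sets matched
#' on a covariate such as cDNA length. Null sets draw, within each covariate
#' quantile bin, the same number of genes as the observed set contributes to
#' that bin (without replacement), which removes confounding of the
#' indicator with the covariate.
#'
#' Within a bin the null count of indicator-true genes is hypergeometric, so
#' null draws sum independent hypergeometric samples per bin — exactly
#' equivalent to permuting gene labels within bins.
#'
#' @param gene_table tibble with `gene_id`, a logical indicator column, and
#'   a numeric covariate column.
#' @param gene_set character vector of gene ids (subset of `gene_table`).
#' @param indicator name of the logical column (default `"indicator"`).
#' @param covariate name of the numeric column (default `"cdna_length"`);
#'   `NULL` for an unmatched test (a single bin).
#' @param n_bins number of quantile bins (default 10, deciles).
#' @param n_perm,seed,direction as in [shuffle_overlap_test()].
#' @return a `perm_test` object; `observed` is the number of set genes with
#'   the indicator true.
#' @export
geneset_permutation_enrich <- function(gene_table, gene_set,
                                       indicator = "indicator",
                                       covariate = "cdna_length",
                                       n_bins = 10, n_perm = 10000,
                                       seed = 1, direction = "greater") {
  if (!all(gene_set %in% gene_table$gene_id)) {
    abort("gene_set contains ids absent from gene_table")
  }
  ind <- gene_table[[indicator]]
  if (is.null(ind)) abort(sprintf("no indicator column '%s'", indicator))
  if (anyNA(ind)) abort("indicator contains NA")
  in_set <- gene_table$gene_id %in% gene_set
  if (is.null(covariate)) {
    bin <- rep(1L, nrow(gene_table))
  } else {
    cov <- gene_table[[covariate]]
    if (is.null(cov) || anyNA(cov)) {
      abort(sprintf("covariate '%s' missing or has NA", covariate))
    }
    breaks <- unique(stats::quantile(cov, probs = seq(0, 1,
                                                      length.out = n_bins + 1)))
    bin <- cut(cov, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  }
  observed <- sum(ind[in_set])
  per_bin <- tibble(bin = bin, ind = ind, in_set = in_set) |>
    group_by(.data$bin) |>
    summarise(m_true = sum(.data$ind), m_false = sum(!.data$ind),
              k = sum(.data$in_set), .groups = "drop") |>
    filter(.data$k > 0)
  short <- per_bin |> filter(.data$k > .data$m_true + .data$m_false)
  if (nrow(short) > 0) {
    abort("a covariate bin has fewer genes than required draws; use fewer bins")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_draws <- rep(0L, n_perm)
  for (j in seq_len(nrow(per_bin))) {
    null_draws <- null_draws + stats::rhyper(n_perm, per_bin$m_true[j],
                                             per_bin$m_false[j],
                                             per_bin$k[j])
  }
  new_perm_test(observed, null_draws, n_perm, seed, direction,
                statistic = "n_set_with_indicator")
}

# Seed hygiene: tests and pipelines around these functions should not have
# their RNG stream disturbed, so the global seed is saved and restored.
#' @noRd
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

#' @noRd
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
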