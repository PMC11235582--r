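# Contingency statistics: 2x2 chi-squared / Fisher, gene-set Fisher
# enrichment with multiplicity correction, VISTA-style per-tissue odds
# ratios, and the DEX filter.

#' Chi-squared and Fisher statistics for a 2x2 table
#'
#' Pearson chi-squared without continuity correction (df = 1), the sample
#' odds ratio `ad/bc`, and the two-sided Fisher exact p. When a table cell
#' is zero the odds ratio uses the Haldane-Anscombe +0.5 adjustment on all
#' cells and is flagged (`or_adjusted`); chi-squared and Fisher p are always
#' computed on the raw counts. With a zero row or column margin the
#' chi-squared statistic is undefined and reported `NA`.
#'
#' @param a,b,c,d non-negative integer cell counts, laid out
#'   `rbind(c(a, b), c(c, d))`.
#' @return a `contingency_test` object (also a one-row tibble): `a`, `b`,
#'   `c`, `d`, `n`, `chi2`, `p_chi2`, `odds_ratio`, `or_adjusted`,
#'   `p_fisher`.
#' @examples
#' contingency_test(96, 6, 11420, 5962)
#' @export
contingency_test <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cells must be non-negative integers")
  }
  # doubles: margin products overflow 32-bit integers at genome scale
  cells <- as.double(cells)
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  n <- sum(cells)
  if (n == 0) abort("empty table")
  margins_ok <- all(c(a + b, c + d, a + c, b + d) > 0)
  if (margins_ok) {
    chi2 <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    p_chi2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    chi2 <- NA_real_
    p_chi2 <- NA_real_
  }
  or_adjusted <- any(cells == 0)
  odds_ratio <- if (or_adjusted) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  p_fisher <- stats::fisher.test(rbind(c(a, b), c(c, d)),
                                 alternative = "two.sided")$p.value
  out <- tibble(a = a, b = b, c = c, d = d, n = n, chi2 = chi2,
                p_chi2 = p_chi2, odds_ratio = odds_ratio,
                or_adjusted = or_adjusted, p_fisher = p_fisher)
  class(out) <- c("contingency_test", class(out))
  out
}

#' Fisher enrichment of a target gene set against a collection of gene sets
#'
#' One 2x2 table per gene set — membership of the target set crossed with
#' membership of the query set, within a fixed gene universe — with
#' two-sided Fisher exact tests and family-wise (`"bonferroni"`) or FDR
#' (`"BH"`) correction across sets.
#'
#' @param target_set character vector (e.g., DEX genes), subset of universe.
#' @param gene_sets named list of character vectors (e.g., coexpression
#'   modules), each a subset of universe.
#' @param universe character vector of all eligible gene ids.
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return tibble: one row per gene set with cells, `odds_ratio`,
#'   `p_fisher`, `p_adj`, `method`.
#' @export
geneset_fisher_enrich <- function(target_set, gene_sets, universe,
                                  correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (length(universe) == 0) abort("empty universe")
  universe <- unique(universe)
  target_set <- intersect(unique(target_set), universe)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    abort("gene_sets must be a named list")
  }
  rows <- imap(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    a <- length(intersect(target_set, set))
    b <- length(setdiff(target_set, set))
    c <- length(setdiff(set, target_set))
    d <- length(universe) - a - b - c
    ct <- contingency_test(a, b, c, d)
    tibble(set = nm, a = a, b = b, c = c, d = d,
           odds_ratio = ct$odds_ratio, or_adjusted = ct$or_adjusted,
           p_fisher = ct$p_fisher)
  })
  out <- list_rbind(rows) |>
    mutate(p_adj = stats::p.adjust(.data$p_fisher, method = correction),
           method = correction)
  out
}

#' DEX criteria for differential-expression filtering
#'
#' @param min_abs_fold_change minimum absolute (linear) fold change,
#'   inclusive (default 2).
#' @param max_adj_p maximum adjusted p, inclusive (default 0.05).
#' @return a `dex_criteria` list.
#' @export
dex_criteria <- function(min_abs_fold_change = 2, max_adj_p = 0.05) {
  if (min_abs_fold_change <= 1) abort("fold-change threshold must be > 1")
  if (max_adj_p <= 0 || max_adj_p >= 1) abort("p threshold must be in (0,1)")
  structure(list(min_abs_fold_change = min_abs_fold_change,
                 max_adj_p = max_adj_p), class = "dex_criteria")
}

#' Filter a differential-expression table into up/down gene sets
#'
#' Thresholds are inclusive: a gene at exactly the fold-change or adjusted-p
#' boundary is retained. With the default criteria, up-regulated means
#' `log2FC >= 1` and `p.adj <= 0.05`; down-regulated `log2FC <= -1`.
#'
#' @param dge_table tibble with columns `gene_id`, `log2fc`, `padj`.
#' @param criteria a [dex_criteria()].
#' @return list: `up`, `down` (character vectors, disjoint), `criteria`.
#' @export
dex_filter <- function(dge_table, criteria = dex_criteria()) {
  need <- c("gene_id", "log2fc", "padj")
  missing_cols <- setdiff(need, names(dge_table))
  if (length(missing_cols) > 0) {
    abort(sprintf("dge_table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  lfc_min <- log2(criteria$min_abs_fold_change)
  sig <- !is.na(dge_table$padj) & dge_table$padj <= criteria$max_adj_p &
    !is.na(dge_table$log2fc)
  list(up = dge_table$gene_id[sig & dge_table$log2fc >= lfc_min],
       down = dge_table$gene_id[sig & dge_table$log2fc <= -lfc_min],
       criteria = criteria)
}

#' Per-tissue enhancer-activity enrichment (VISTA-style)
#'
#' For each tissue with at least `min_positive_per_tissue` positive
#' elements, builds the 2x2 table of (element overlaps a qualifying locus) x
#' (element positive in tissue), tests with two-sided Fisher, and corrects
#' across retained tissues by BH-FDR. Tissues below the filter are excluded
#' (small-sample tissues are uninformative and would dilute the FDR).
#'
#' @param vista_table tibble, one row per element x tissue: `element_id`,
#'   `chrom`, `start`, `end`, `tissue`, `positive` (logical).
#' @param qualifying_loci interval tibble (e.g., distal >= 3TR + ATAC loci).
#' @param min_positive_per_tissue exclusion threshold (default 50; tissues
#'   with fewer positives are dropped).
#' @return tibble: per retained tissue `n_positive`, cells, `odds_ratio`,
#'   `or_adjusted`, `p_fisher`, `p_adj`.
#' @export
vista_tissue_enrichment <- function(vista_table, qualifying_loci,
                                    min_positive_per_tissue = 50) {
  need <- c("element_id", "chrom", "start", "end", "tissue", "positive")
  missing_cols <- setdiff(need, names(vista_table))
  if (length(missing_cols) > 0) {
    abort(sprintf("vista_table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  elements <- vista_table |>
    distinct(.data$element_id, .data$chrom, .data$start, .data$end)
  hit <- GenomicRanges::countOverlaps(
    as_granges(elements |> select("chrom", "start", "end")),
    as_granges(qualifying_loci |> select("chrom", "start", "end")),
    ignore.strand = TRUE) > 0
  elements$overlaps_locus <- hit
  long <- vista_table |>
    left_join(elements |> select("element_id", "overlaps_locus"),
              by = "element_id")
  retained <- long |>
    group_by(.data$tissue) |>
    summarise(n_positive = sum(.data$positive), .groups = "drop") |>
    filter(.data$n_positive >= min_positive_per_tissue)
  if (nrow(retained) == 0) abort("no tissue passes the positive-count filter")
  rows <- map(retained$tissue, function(ti) {
    d <- long |> filter(.data$tissue == ti)
    a <- sum(d$overlaps_locus & d$positive)
    b <- sum(d$overlaps_locus & !d$positive)
    c <- sum(!d$overlaps_locus & d$positive)
    dd <- sum(!d$overlaps_locus & !d$positive)
    ct <- contingency_test(a, b, c, dd)
    tibble(tissue = ti, n_positive = a + c, a = a, b = b, c = c, d = dd,
           odds_ratio = ct$odds_ratio, or_adjusted = ct$or_adjusted,
           p_fisher = ct$p_fisher)
  })
  list_rbind(rows) |>
    mutate(p_adj = stats::p.adjust(.data$p_fisher, method = "BH"))
}
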