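# Rank-based cross-dataset concordance of peak lists: top-N selection by
# peak-caller p-value, pairwise intersection percentage, Spearman rho of the
# intersecting rank lists, and panel-level comparison.

#' Select the top-N peaks of an assay by p-value rank
#'
#' Peaks are ordered by ascending p-value (descending `score_neglog10p`),
#' with ties broken by genomic location (`chrom`, `start`, `end`,
#' lexicographic) so the order is total and deterministic. Peaks without a
#' usable p-value (the peak-caller sentinel) are excluded from ranking.
#'
#' @param peaks peak tibble with `score_neglog10p`.
#' @param n number of peaks to keep; error (naming the counts) if fewer
#'   rankable peaks are available.
#' @return tibble of the top `n` peaks with a 1-based `rank` column;
#'   attribute `n_selected`.
#' @export
rank_top_n <- function(peaks, n) {
  ranked <- peaks |>
    filter(!is.na(.data$score_neglog10p)) |>
    arrange(desc(.data$score_neglog10p), .data$chrom, .data$start, .data$end)
  if (nrow(ranked) < n) {
    abort(sprintf("requested top %d peaks but only %d have p-values",
                  n, nrow(ranked)))
  }
  out <- ranked |> slice_head(n = n) |> mutate(rank = row_number())
  attr(out, "n_selected") <- n
  out
}

#' Intersection percentage and rank correlation for a pair of ranked lists
#'
#' Each peak of list A is matched to the best-overlapping peak of list B
#' (largest bp overlap; ties to the better B rank), any overlap counting.
#' `intersect_pct` is the percentage of A peaks matched. Spearman's rho is
#' computed over the matched pairs' within-top-N ranks (average-rank ties),
#' and is reported `NA` with fewer than two matched pairs.
#'
#' @param list_a,list_b outputs of [rank_top_n()] with equal `n`.
#' @return one-row tibble `n`, `n_matched`, `intersect_pct`, `rho`.
#' @export
pairwise_concordance <- function(list_a, list_b) {
  n <- attr(list_a, "n_selected") %||% nrow(list_a)
  nb <- attr(list_b, "n_selected") %||% nrow(list_b)
  if (n != nb) abort("lists were ranked with different n")
  matched <- match_best_overlap(list_a, list_b)
  tibble(n = n, n_matched = nrow(matched),
         intersect_pct = pct(nrow(matched), n),
         rho = rank_rho(matched))
}

#' @noRd
rank_rho <- function(matched) {
  if (nrow(matched) < 2) return(NA_real_)
  suppressWarnings(
    stats::cor(matched$rank_a, matched$rank_b, method = "spearman"))
}

# Match each A peak to its best-overlapping B peak (largest bp overlap,
# ties -> smallest B rank). Many-to-one: several A peaks may share a B peak.
#' @noRd
match_best_overlap <- function(list_a, list_b, hits = NULL) {
  if (is.null(hits)) {
    hits <- GenomicRanges::findOverlaps(
      as_granges(list_a |> select("chrom", "start", "end")),
      as_granges(list_b |> select("chrom", "start", "end")),
      ignore.strand = TRUE)
  }
  if (length(hits) == 0) {
    return(tibble(rank_a = integer(), rank_b = integer()))
  }
  qa <- S4Vectors::queryHits(hits)
  sb <- S4Vectors::subjectHits(hits)
  ov_bp <- pmin(list_a$end[qa], list_b$end[sb]) -
    pmax(list_a$start[qa], list_b$start[sb])
  rank_b <- list_b$rank[sb]
  o <- order(qa, -ov_bp, rank_b)
  keep <- o[!duplicated(qa[o])]
  tibble(rank_a = list_a$rank[qa[keep]], rank_b = rank_b[keep])
}

# swap the roles of query and subject in a hits object, as a plain tibble
#' @noRd
swap_hits <- function(hits) {
  S4Vectors::Hits(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits),
                  S4Vectors::nRnode(hits), S4Vectors::nLnode(hits),
                  sort.by.query = TRUE)
}

#' All-pairs concordance across a panel of peak sets
#'
#' Applies [rank_top_n()] per assay and [pairwise_concordance()] per
#' unordered pair. Rho is symmetric by construction (computed once per pair
#' with A the lexicographically lower label); intersection is directional
#' and reported both ways.
#'
#' @param peaksets named list of peak tibbles (>= 2), or a single tibble
#'   with an `assay` column.
#' @param n top-N cut applied to every assay.
#' @param class optional `"proximal"`/`"distal"` filter applied first
#'   (requires a `class` column from [classify_peaks()]).
#' @return tibble of class `panel_concordance`: `assay_a`, `assay_b`
#'   (a < b), `n`, `intersect_pct_ab`, `intersect_pct_ba`, `rho`.
#' @export
panel_concordance <- function(peaksets, n, class = NULL) {
  if (is.data.frame(peaksets)) {
    peaksets <- split(peaksets, peaksets$assay)
  }
  if (length(peaksets) < 2) abort("need at least two peak sets")
  if (!is.null(class)) {
    cls <- class
    peaksets <- map(peaksets, ~ filter(.x, .data$class == cls))
  }
  ranked <- map(peaksets, rank_top_n, n = n)
  labels <- sort(names(ranked))
  grs <- map(ranked, ~ as_granges(select(.x, "chrom", "start", "end")))
  pairs <- utils::combn(labels, 2, simplify = FALSE)
  out <- map(pairs, function(p) {
    la <- ranked[[p[1]]]; lb <- ranked[[p[2]]]
    hits <- GenomicRanges::findOverlaps(grs[[p[1]]], grs[[p[2]]],
                                        ignore.strand = TRUE)
    m_ab <- match_best_overlap(la, lb, hits)
    m_ba <- match_best_overlap(lb, la, swap_hits(hits))
    tibble(assay_a = p[1], assay_b = p[2], n = n,
           intersect_pct_ab = pct(nrow(m_ab), n),
           intersect_pct_ba = pct(nrow(m_ba), n),
           rho = rank_rho(m_ab))
  }) |> list_rbind()
  class(out) <- c("panel_concordance", class(out))
  out
}

#' Compare two panels of pairwise concordance statistics
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test on a chosen pairwise
#' statistic (rho by default) between two panels — e.g., a co-binding panel
#' in one tissue versus an unrelated panel in another. Exact p for small
#' samples (<= 25 retained values in total, no ties), normal approximation
#' with tie correction otherwise. TR pairs can be excluded (e.g., a
#' structurally coupled pair like CTCF-RAD21).
#'
#' @param panel_a,panel_b outputs of [panel_concordance()].
#' @param statistic column to compare (`"rho"` or an intersect column).
#' @param exclusions list of length-2 character vectors naming assay pairs
#'   to drop (order-free), applied to both panels.
#' @return list of class `panel_comparison`: `statistic`, `values_a`,
#'   `values_b`, `wilcoxon_w`, `wilcoxon_p`, `median_a`, `median_b`,
#'   `exclusions`.
#' @export
compare_panels <- function(panel_a, panel_b, statistic = "rho",
                           exclusions = list()) {
  drop_pairs <- function(panel) {
    if (length(exclusions) == 0) return(panel)
    keep <- !map_lgl(seq_len(nrow(panel)), function(i) {
      any(map_lgl(exclusions, ~ setequal(.x, c(panel$assay_a[i],
                                               panel$assay_b[i]))))
    })
    panel[keep, , drop = FALSE]
  }
  a <- stats::na.omit(drop_pairs(panel_a)[[statistic]])
  b <- stats::na.omit(drop_pairs(panel_b)[[statistic]])
  if (length(a) == 0 || length(b) == 0) abort("empty panel after exclusion")
  wt <- wilcox_ranksum(a, b)
  structure(list(statistic = statistic, values_a = a, values_b = b,
                 wilcoxon_w = wt$w, wilcoxon_p = wt$p,
                 median_a = stats::median(a), median_b = stats::median(b),
                 exclusions = exclusions),
            class = "panel_comparison")
}

# Two-sided rank-sum p: exact when feasible and small, else normal
# approximation with tie-corrected variance. All-equal input degenerates to
# p = 1 (no evidence of shift).
#' @noRd
wilcox_ranksum <- function(a, b) {
  if (length(unique(c(a, b))) == 1) {
    return(list(w = length(a) * length(b) / 2, p = 1))
  }
  use_exact <- (length(a) + length(b)) <= 25 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = FALSE))
  list(w = unname(wt$statistic), p = wt$p.value)
}

#' @export
print.panel_comparison <- function(x, ...) {
  cat(sprintf("Panel comparison on %s: median %.3f vs %.3f, W = %.1f, p = %.3g\n",
              x$statistic, x$median_a, x$median_b, x$wilcoxon_w,
              x$wilcoxon_p))
  if (length(x$exclusions) > 0) {
    cat("Excluded pairs:",
        paste(map_chr(x$exclusions, paste, collapse = "-"), collapse = ", "),
        "\n")
  }
  invisible(x)
}
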