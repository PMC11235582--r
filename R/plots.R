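# ggplot2 figures for the main result types.

#' @import ggplot2
NULL

#' Heat-matrix of pairwise panel concordance
#'
#' Lower triangle shows Spearman rho, mirrored; diagonal is blank. The
#' standard view of cross-regulator rank concordance.
#'
#' @param object a `panel_concordance` from [panel_concordance()].
#' @param value `"rho"` (default) or an intersect column.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.panel_concordance <- function(object, value = "rho", ...) {
  d <- bind_rows(
    object |> select(a = "assay_a", b = "assay_b",
                     value = all_of(value)),
    object |> select(a = "assay_b", b = "assay_a",
                     value = all_of(value)))
  ggplot(d, aes(x = .data$a, y = .data$b, fill = .data$value)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$value)), size = 3) +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick", midpoint = 0, name = value) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Bar chart of loci by regulator count, split by open chromatin
#'
#' @param counts output of [membership_counts()].
#' @param class_filter `"proximal"` (default) or `"distal"`.
#' @return a ggplot.
#' @export
plot_membership <- function(counts, class_filter = "proximal") {
  d <- counts$by_tr_count |> filter(.data$class == class_filter) |>
    tidyr::pivot_longer(c("n_atac", "n"), names_to = "which",
                        values_to = "count") |>
    mutate(which = ifelse(.data$which == "n_atac", "with ATAC", "all"))
  ggplot(d, aes(x = factor(.data$tr_count), y = .data$count,
                fill = .data$which)) +
    geom_col(position = "dodge") +
    labs(x = "regulators bound", y = sprintf("%s loci", class_filter),
         fill = NULL) +
    theme_minimal()
}

#' Null distribution of a permutation test with the observed value
#'
#' @param x a `perm_test`.
#' @return a ggplot.
#' @export
plot_perm_null <- function(x) {
  ggplot(tibble(null = x$null_draws), aes(x = .data$null)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = x$observed, colour = "firebrick",
               linewidth = 1) +
    labs(x = x$statistic, y = "permutations",
         subtitle = sprintf("observed = %.4g, empirical p = %.3g",
                            x$observed, x$p_empirical)) +
    theme_minimal()
}

#' Expression by proximal regulator count
#'
#' Median with interquartile range per regulator-count stratum; the
#' signature expected of convergent activating regulation is a monotone
#' rise.
#'
#' @param x an `expression_strata` from [expression_stratify()].
#' @return a ggplot.
#' @export
plot_expression_strata <- function(x) {
  ggplot(x$by_tr_count,
         aes(x = factor(.data$proximal_tr_count), y = .data$median)) +
    geom_pointrange(aes(ymin = .data$q1, ymax = .data$q3)) +
    geom_hline(yintercept = x$robust_threshold, linetype = "dashed",
               colour = "grey50") +
    labs(x = "regulators bound proximally", y = "log2(TPM+1)") +
    theme_minimal()
}
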