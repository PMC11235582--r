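# broom-style tidiers for the package's fitted/result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a permutation test
#'
#' @param x a `perm_test` from [shuffle_overlap_test()] or
#'   [geneset_permutation_enrich()].
#' @param ... unused.
#' @return one-row tibble: `statistic`, `observed`, `null_mean`, `null_sd`,
#'   `n_perm`, `n_as_extreme`, `p_empirical`, `direction`, `seed`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble(statistic = x$statistic, observed = x$observed,
         null_mean = x$null_summary$mean, null_sd = x$null_summary$sd,
         n_perm = x$n_perm, n_as_extreme = x$n_as_extreme,
         p_empirical = x$p_empirical, direction = x$direction,
         seed = x$seed)
}

#' @rdname tidy.perm_test
#' @export
glance.perm_test <- function(x, ...) {
  tibble(p_empirical = x$p_empirical, n_perm = x$n_perm, seed = x$seed)
}

#' Tidy a 2x2 contingency test
#'
#' @param x a `contingency_test`.
#' @param ... unused.
#' @return one-row tibble with the cells, `chi2`, `p_chi2`, `odds_ratio`,
#'   `p_fisher`.
#' @export
tidy.contingency_test <- function(x, ...) as_tibble(unclass(x))

#' @rdname tidy.contingency_test
#' @export
glance.contingency_test <- function(x, ...) {
  tibble(chi2 = x$chi2, p_chi2 = x$p_chi2, odds_ratio = x$odds_ratio,
         p_fisher = x$p_fisher, n = x$n)
}

#' Tidy a panel comparison
#'
#' @param x a `panel_comparison` from [compare_panels()].
#' @param ... unused.
#' @return one-row tibble: `statistic`, medians, sizes, `wilcoxon_w`,
#'   `wilcoxon_p`.
#' @export
tidy.panel_comparison <- function(x, ...) {
  tibble(statistic = x$statistic,
         n_a = length(x$values_a), n_b = length(x$values_b),
         median_a = x$median_a, median_b = x$median_b,
         wilcoxon_w = x$wilcoxon_w, wilcoxon_p = x$wilcoxon_p)
}

#' Tidy expression strata
#'
#' @param x an `expression_strata` from [expression_stratify()].
#' @param ... unused.
#' @return the per-stratum summary tibble.
#' @export
tidy.expression_strata <- function(x, ...) x$strata

#' @rdname tidy.expression_strata
#' @export
glance.expression_strata <- function(x, ...) {
  tibble(n_genes = sum(x$strata$n),
         n_strata = sum(x$strata$n > 0),
         robust_threshold = x$robust_threshold,
         model_fitted = !is.null(x$model))
}
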