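# Expression stratification by proximal regulator count, and relative qPCR
# quantification (delta-delta-Ct).

#' Per-gene proximal binding profile
#'
#' For each gene: the number of distinct TR assays with a proximal locus
#' overlapping the gene's promoter windows (`proximal_tr_count`), whether
#' any such locus carries the ATAC flag (`proximal_atac`), and whether a
#' qualifying distal locus lies within the linking window (`distal_link`).
#'
#' @param genes per-gene tibble from [gene_models()].
#' @param promoters promoter tibble from [build_promoters()].
#' @param locus_table tibble from [merge_loci()].
#' @param config [link_config()] used for the distal flag; `NULL` skips it.
#' @return tibble `gene_id`, `proximal_tr_count`, `proximal_atac`,
#'   `distal_link`.
#' @export
gene_binding_profile <- function(genes, promoters, locus_table,
                                 config = link_config()) {
  prox <- locus_table |> filter(.data$class == "proximal")
  profile <- tibble(gene_id = genes$gene_id,
                    proximal_tr_count = 0L,
                    proximal_atac = FALSE)
  if (nrow(prox) > 0 && nrow(promoters) > 0) {
    hits <- GenomicRanges::findOverlaps(
      as_granges(promoters |> select("chrom", "start", "end")),
      as_granges(prox |> select("chrom", "start", "end")),
      ignore.strand = TRUE)
    if (length(hits) > 0) {
      per_gene <- tibble(
        gene_id = promoters$gene_id[S4Vectors::queryHits(hits)],
        locus = S4Vectors::subjectHits(hits)) |>
        group_by(.data$gene_id) |>
        summarise(
          proximal_tr_count =
            length(unique(unlist(prox$membership[unique(.data$locus)]))),
          proximal_atac = any(prox$atac[unique(.data$locus)]),
          .groups = "drop")
      m <- match(per_gene$gene_id, profile$gene_id)
      profile$proximal_tr_count[m] <- per_gene$proximal_tr_count
      profile$proximal_atac[m] <- per_gene$proximal_atac
    }
  }
  if (!is.null(config)) {
    linked <- link_distal_to_genes(locus_table, genes, config)$linked
    w_max <- max(config$windows_bp)
    linked_genes <- linked$gene_id[linked$window_bp == w_max]
    profile$distal_link <- profile$gene_id %in% linked_genes
  } else {
    profile$distal_link <- FALSE
  }
  profile
}

#' Stratify gene expression by proximal regulator count
#'
#' Genes are stratified by (proximal TR count) x (proximal ATAC yes/no) x
#' (qualifying distal locus yes/no). Each stratum reports n, the median and
#' quartiles of log2(TPM+1), and the fraction of genes robustly expressed
#' (log2(TPM+1) >= `robust_threshold`). A standard maximum-likelihood
#' logistic model of robust expression on the stratum indicators is fitted
#' alongside (Wald z tests).
#'
#' @param binding_profile tibble from [gene_binding_profile()].
#' @param expression tibble `gene_id`, `log2_tpm1`; genes without an
#'   expression record are dropped with a warning.
#' @param robust_threshold robust-expression cut on log2(TPM+1), default 1.
#' @return list of class `expression_strata`: `strata` (per-stratum
#'   summaries, n = 0 rows kept), `by_tr_count` (marginal over TR count),
#'   `model` (tidy coefficient tibble or `NULL` if the fit is degenerate),
#'   `robust_threshold`.
#' @export
expression_stratify <- function(binding_profile, expression,
                                robust_threshold = 1) {
  if (any(expression$log2_tpm1 < 0)) abort("log2_tpm1 must be >= 0")
  d <- binding_profile |>
    inner_join(expression |> select("gene_id", "log2_tpm1"), by = "gene_id")
  if (nrow(d) < nrow(binding_profile)) {
    warn(sprintf("%d gene(s) without expression dropped",
                 nrow(binding_profile) - nrow(d)))
  }
  if (nrow(d) == 0) abort("no genes with both binding profile and expression")
  d <- d |> mutate(robust = .data$log2_tpm1 >= robust_threshold)
  grid <- tidyr::expand_grid(
    proximal_tr_count = sort(unique(binding_profile$proximal_tr_count)),
    proximal_atac = c(FALSE, TRUE),
    distal_link = c(FALSE, TRUE))
  strata <- d |>
    group_by(.data$proximal_tr_count, .data$proximal_atac,
             .data$distal_link) |>
    summarise(n = n(),
              median = stats::median(.data$log2_tpm1),
              q1 = unname(stats::quantile(.data$log2_tpm1, 0.25)),
              q3 = unname(stats::quantile(.data$log2_tpm1, 0.75)),
              frac_robust = mean(.data$robust),
              .groups = "drop")
  strata <- grid |>
    left_join(strata,
              by = c("proximal_tr_count", "proximal_atac", "distal_link")) |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
  by_tr_count <- d |>
    group_by(.data$proximal_tr_count) |>
    summarise(n = n(),
              median = stats::median(.data$log2_tpm1),
              q1 = unname(stats::quantile(.data$log2_tpm1, 0.25)),
              q3 = unname(stats::quantile(.data$log2_tpm1, 0.75)),
              frac_robust = mean(.data$robust),
              .groups = "drop") |>
    arrange(.data$proximal_tr_count)
  model <- NULL
  if (length(unique(d$robust)) == 2) {
    fit <- stats::glm(
      robust ~ factor(proximal_tr_count) + proximal_atac + distal_link,
      family = stats::binomial(), data = d)
    cf <- summary(fit)$coefficients
    model <- tibble(term = rownames(cf), estimate = cf[, 1],
                    std_error = cf[, 2], statistic = cf[, 3],
                    p_value = cf[, 4])
  }
  structure(list(strata = strata, by_tr_count = by_tr_count, model = model,
                 robust_threshold = robust_threshold),
            class = "expression_strata")
}

#' @export
print.expression_strata <- function(x, ...) {
  cat(sprintf("Expression strata (robust: log2(TPM+1) >= %g)\n",
              x$robust_threshold))
  print(x$by_tr_count)
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `dCt = Ct_target - Ct_housekeeping` per condition (several housekeeping
#' genes are combined by the arithmetic mean of their Ct values),
#' `ddCt = dCt_treated - dCt_control`, and relative expression
#' `2^(-ddCt)` (1 means no change; `ddCt = -1` a doubling).
#'
#' @param ct_target,ct_housekeeping Ct values in the treated condition
#'   (`ct_housekeeping` may be a vector of housekeeping-gene Cts).
#' @param ct_target_ctrl,ct_housekeeping_ctrl same for the control
#'   condition.
#' @return one-row tibble `delta_ct`, `delta_ct_ctrl`, `delta_delta_ct`,
#'   `rel_expression`.
#' @examples
#' ddct(22, 18, 20, 18)   # ddCt = 2, 4-fold decrease
#' @export
ddct <- function(ct_target, ct_housekeeping, ct_target_ctrl,
                 ct_housekeeping_ctrl) {
  vals <- c(ct_target, ct_housekeeping, ct_target_ctrl, ct_housekeeping_ctrl)
  if (any(!is.finite(vals))) abort("Ct values must be finite")
  d_ct <- ct_target - mean(ct_housekeeping)
  d_ct_ctrl <- ct_target_ctrl - mean(ct_housekeeping_ctrl)
  dd_ct <- d_ct - d_ct_ctrl
  tibble(delta_ct = d_ct, delta_ct_ctrl = d_ct_ctrl,
         delta_delta_ct = dd_ct, rel_expression = 2^(-dd_ct))
}
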