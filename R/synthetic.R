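# Synthetic-data generator with a ground-truth ledger. Emulates the
# statistical structure the pipeline is built to detect: a fraction of
# promoters ("hubs") co-bound by all five regulators plus open chromatin,
# independent background binding elsewhere, peak p-value ranks coupled
# across regulators at hubs, expression increasing with bound-regulator
# count, conservation elevated at hubs, and a gene set optionally
# confounded with cDNA length.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a desk-scale genome: 5 chromosomes of 1 Mb, 1,000
#' genes on a ~5 kb spacing, 2 kb promoters, 30% hub promoters where all
#' five regulators and ATAC co-bind, 10% independent per-regulator binding
#' elsewhere, log-normal peak lengths (median ~600 bp, typical of
#' narrow-peak transcription-factor calls), strong rank coupling at hubs,
#' and expression rising ~0.5 log2(TPM+1) per bound regulator.
#'
#' @param seed integer seed; the same seed gives byte-identical fixtures.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of genes; `max_transcripts` TSSs per gene are drawn
#'   uniformly from 1..max, extra TSSs within 400 bp downstream.
#' @param promoter_window promoter length in bp.
#' @param hub_fraction fraction of genes whose promoter is a five-TR + ATAC
#'   hub.
#' @param distal_hub_fraction fraction of genes with an additional co-bound
#'   distal site (ARID1B/BCL11A/TBR1 + ATAC) 5-80 kb from the TSS.
#' @param tr_rate independent per-regulator binding probability at non-hub
#'   promoters.
#' @param atac_rate open-chromatin probability at non-hub promoters.
#' @param n_background_peaks random (mostly distal) peaks per regulator.
#' @param peak_meanlog,peak_sdlog log-normal peak length parameters.
#' @param pvalue_rank_coupling in `[0, 1]`: 1 = identical peak ranking
#'   across regulators at hubs, 0 = independent.
#' @param expr_beta0,expr_beta_tr,expr_beta_atac,expr_sigma expression
#'   model: `log2(TPM+1) = b0 + b_tr * TR_count + b_atac * ATAC + N(0, s)`,
#'   floored at 0.
#' @param geneset_size size of the bundled gene set.
#' @param geneset_hub_bias log-weight favouring hub genes in the set.
#' @param geneset_length_bias log-weight coupling set membership to
#'   standardised log cDNA length (the planted confound).
#' @param binding_length_bias log-weight coupling *hub status* to cDNA
#'   length (creates the indicator-length confound the matched permutation
#'   test must absorb).
#' @param dge_n_up,dge_n_down,dge_lfc planted differential-expression truth.
#' @param tr_names the five regulator assay labels.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_chroms = 5,
                             chrom_length = 1e6,
                             n_genes = 1000,
                             max_transcripts = 3,
                             promoter_window = 2000,
                             hub_fraction = 0.3,
                             distal_hub_fraction = 0.1,
                             tr_rate = 0.1,
                             atac_rate = 0.2,
                             n_background_peaks = 200,
                             peak_meanlog = log(600),
                             peak_sdlog = 0.35,
                             pvalue_rank_coupling = 0.8,
                             expr_beta0 = 0.3,
                             expr_beta_tr = 0.5,
                             expr_beta_atac = 0.5,
                             expr_sigma = 0.5,
                             geneset_size = 102,
                             geneset_hub_bias = 3,
                             geneset_length_bias = 0,
                             binding_length_bias = 0,
                             dge_n_up = 50,
                             dge_n_down = 50,
                             dge_lfc = 2,
                             tr_names = c("ARID1B", "BCL11A", "FOXP1",
                                          "TBR1", "TCF7L2")) {
  cfg <- as.list(environment())
  probs <- c(hub_fraction, distal_hub_fraction, tr_rate, atac_rate,
             pvalue_rank_coupling)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0,1]")
  if (round(hub_fraction * n_genes) > n_genes) abort("too many hub genes")
  if (geneset_size > n_genes) abort("geneset_size exceeds n_genes")
  if (dge_n_up + dge_n_down > n_genes) abort("too many planted DEX genes")
  if (n_genes / n_chroms * 1 > chrom_length / 5000) {
    abort("genome too small for n_genes at ~5 kb spacing")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic fixture bundle with ground truth
#'
#' Produces, in memory, every input the pipeline consumes — peak tibbles per
#' regulator and for ATAC and H3K27ac, a transcript table, expression,
#' a conservation score track, a gene set, and a DGE table — plus a `truth`
#' ledger recording what was planted. Optionally writes all of it to `dir`
#' in the standard plain-text formats (narrowPeak, TSV, bedGraph, YAML).
#' Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory; created if missing.
#' @return list: `genome`, `transcripts`, `genes`, `tr_peaks` (named list),
#'   `atac_peaks`, `histone_peaks`, `expression`, `score_track`, `gene_set`,
#'   `dge_table`, `truth`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  cfg <- config

  genome <- genome_def(paste0("chr", seq_len(cfg$n_chroms)),
                       rep(cfg$chrom_length, cfg$n_chroms))

  ## --- gene models on a jittered grid (promoters well separated) ---------
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  spacing <- floor((cfg$chrom_length - 10000) / per_chrom)
  g <- tibble(
    gene_id = sprintf("G%04d", seq_len(cfg$n_genes)),
    chrom = genome$chrom[((seq_len(cfg$n_genes) - 1) %% cfg$n_chroms) + 1],
    slot = ((seq_len(cfg$n_genes) - 1) %/% cfg$n_chroms)
  ) |>
    mutate(
      tss1 = 5000 + .data$slot * spacing +
        sample(0:(max(spacing - 4000, 1)), cfg$n_genes, replace = TRUE),
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      cdna_length = pmax(200, round(stats::rlnorm(cfg$n_genes,
                                                  log(2000), 0.6))),
      biotype = sample(c("protein_coding", "non_coding"), cfg$n_genes,
                       replace = TRUE, prob = c(0.85, 0.15)),
      n_tx = sample(seq_len(cfg$max_transcripts), cfg$n_genes,
                    replace = TRUE)
    )
  transcripts <- g |>
    mutate(extra = map(.data$n_tx, function(k) {
      if (k == 1) integer() else sort(sample(50:400, k - 1))
    }))
  # extra TSSs lie downstream (3') of the primary TSS, strand-aware
  transcripts$tss_all <- pmap(
    list(g$tss1, transcripts$extra, g$strand),
    function(t, e, s) if (length(e) == 0) t
    else c(t, if (s == "+") t + e else t - e))
  transcripts <- transcripts |>
    select("gene_id", "chrom", "strand", "cdna_length", "biotype",
           "tss_all") |>
    tidyr::unnest(cols = "tss_all") |>
    rename(tss = "tss_all") |>
    group_by(.data$gene_id) |>
    mutate(transcript_id = paste0(.data$gene_id[1], ".",
                                  row_number())) |>
    ungroup() |>
    mutate(tss = pmax(3000L, pmin(as.integer(.data$tss),
                                  as.integer(cfg$chrom_length - 3000)))) |>
    select("gene_id", "transcript_id", "chrom", "strand", "tss",
           "cdna_length", "biotype")
  genes <- gene_models(transcripts)

  ## --- hub assignment (optionally length-biased) --------------------------
  z_len <- as.numeric(scale(log(g$cdna_length)))
  n_hub <- round(cfg$hub_fraction * cfg$n_genes)
  hub_w <- exp(cfg$binding_length_bias * z_len)
  hub_genes <- if (n_hub > 0) {
    sample(g$gene_id, n_hub, prob = hub_w)
  } else character()
  is_hub <- g$gene_id %in% hub_genes
  n_dhub <- round(cfg$distal_hub_fraction * cfg$n_genes)
  distal_hub_genes <- if (n_dhub > 0) sample(g$gene_id, n_dhub) else character()

  ## --- promoter anchors ----------------------------------------------------
  # promoter midpoint: centre of the window immediately 5' of the primary
  # TSS (the 5'-most transcribed base: min on +, max on - strand)
  tss_lists <- genes$tss_list[match(g$gene_id, genes$gene_id)]
  first_tss <- map2_dbl(tss_lists, g$strand,
                        function(t, s) if (s == "+") min(t) else max(t))
  prom_mid <- ifelse(g$strand == "+",
                     first_tss - cfg$promoter_window / 2,
                     first_tss + 1 + cfg$promoter_window / 2)
  # one shared distal co-bound site per distal-hub gene
  dh_idx <- which(g$gene_id %in% distal_hub_genes)
  dh_center <- first_tss[dh_idx] +
    sample(c(-1, 1), length(dh_idx), replace = TRUE) *
    stats::runif(length(dh_idx), 5000, 80000)
  dh_center <- pmin(pmax(dh_center, 1000), cfg$chrom_length - 1000)

  rlen <- function(n) pmax(50, round(stats::rlnorm(n, cfg$peak_meanlog,
                                                   cfg$peak_sdlog)))
  clip_peak <- function(tbl) {
    tbl |>
      mutate(start = pmax(.data$start, 0),
             end = pmin(.data$end, cfg$chrom_length)) |>
      filter(.data$start < .data$end)
  }
  mk_peaks <- function(centers, chroms, assay, scores) {
    n <- length(centers)
    len <- rlen(n)
    clip_peak(tibble(
      chrom = chroms,
      start = as.integer(round(centers - len / 2)),
      end = as.integer(round(centers - len / 2) + len),
      name = sprintf("%s_%05d", assay, seq_len(n)),
      strand = ".",
      score_neglog10p = scores,
      assay = assay))
  }

  ## --- regulator peaks -----------------------------------------------------
  latent <- stats::rnorm(cfg$n_genes)  # shared hub ranking
  rc <- cfg$pvalue_rank_coupling
  tr_bound <- matrix(FALSE, cfg$n_genes, length(cfg$tr_names),
                     dimnames = list(g$gene_id, cfg$tr_names))
  tr_peaks <- list()
  for (j in seq_along(cfg$tr_names)) {
    tr <- cfg$tr_names[j]
    bound <- is_hub | (stats::runif(cfg$n_genes) < cfg$tr_rate)
    tr_bound[, j] <- bound
    idx <- which(bound)
    x <- rc * latent[idx] + sqrt(1 - rc^2) * stats::rnorm(length(idx))
    x[!is_hub[idx]] <- stats::rnorm(sum(!is_hub[idx]))  # no coupling off-hub
    scores <- exp(1 + 0.8 * x)
    jitter <- stats::runif(length(idx), -500, 500)
    prox <- mk_peaks(prom_mid[idx] + jitter, g$chrom[idx], tr, scores)
    # distal co-bound sites for the configured trio
    distal <- NULL
    if (length(dh_idx) > 0 && tr %in% c("ARID1B", "BCL11A", "TBR1")) {
      distal <- mk_peaks(dh_center + stats::runif(length(dh_idx), -500, 500),
                         g$chrom[dh_idx], tr,
                         exp(1 + 0.8 * stats::rnorm(length(dh_idx))))
    }
    bg_chrom <- sample(genome$chrom, cfg$n_background_peaks, replace = TRUE)
    bg <- mk_peaks(stats::runif(cfg$n_background_peaks, 1000,
                                cfg$chrom_length - 1000),
                   bg_chrom, tr,
                   exp(1 + 0.8 * stats::rnorm(cfg$n_background_peaks)))
    pk <- bind_rows(prox, distal, bg) |>
      mutate(name = sprintf("%s_%05d", tr, row_number()))
    tr_peaks[[tr]] <- pk
  }

  ## --- ATAC and H3K27ac ----------------------------------------------------
  atac_at <- is_hub | (stats::runif(cfg$n_genes) < cfg$atac_rate)
  atac_prox <- mk_peaks(prom_mid[atac_at] +
                          stats::runif(sum(atac_at), -500, 500),
                        g$chrom[atac_at], "ATAC",
                        exp(1 + 0.8 * stats::rnorm(sum(atac_at))))
  # distal co-bound sites carry ATAC too
  atac_distal <- NULL
  if (length(dh_idx) > 0) {
    atac_distal <- mk_peaks(dh_center + stats::runif(length(dh_idx),
                                                     -500, 500),
                            g$chrom[dh_idx], "ATAC",
                            exp(1 + 0.8 * stats::rnorm(length(dh_idx))))
  }
  atac_peaks <- bind_rows(atac_prox, atac_distal) |>
    mutate(name = sprintf("ATAC_%05d", row_number()))
  k27_at <- which(atac_at & stats::runif(cfg$n_genes) < 0.8)
  histone_peaks <- list(
    H3K27ac = mk_peaks(prom_mid[k27_at] +
                         stats::runif(length(k27_at), -500, 500),
                       g$chrom[k27_at], "H3K27ac",
                       exp(1 + 0.8 * stats::rnorm(length(k27_at)))))

  ## --- expression ----------------------------------------------------------
  tr_count <- rowSums(tr_bound)
  expression <- tibble(
    gene_id = g$gene_id,
    log2_tpm1 = pmax(0, cfg$expr_beta0 + cfg$expr_beta_tr * tr_count +
                       cfg$expr_beta_atac * as.numeric(atac_at) +
                       stats::rnorm(cfg$n_genes, 0, cfg$expr_sigma)))

  ## --- conservation track (elevated at hub promoters) ---------------------
  prom_start <- ifelse(g$strand == "+", first_tss - cfg$promoter_window,
                       first_tss + 1)
  score_track <- tibble(
    chrom = g$chrom,
    start = as.integer(pmax(prom_start, 0)),
    end = as.integer(pmax(prom_start, 0) + cfg$promoter_window),
    value = ifelse(is_hub, stats::runif(cfg$n_genes, 0.55, 0.95),
                   stats::runif(cfg$n_genes, 0.05, 0.45))) |>
    arrange(.data$chrom, .data$start)

  ## --- gene set (hub- and/or length-biased) --------------------------------
  set_w <- exp(cfg$geneset_hub_bias * is_hub +
                 cfg$geneset_length_bias * z_len)
  gene_set <- sample(g$gene_id, cfg$geneset_size, prob = set_w)

  ## --- DGE table with planted truth ----------------------------------------
  dex_idx <- sample(cfg$n_genes, cfg$dge_n_up + cfg$dge_n_down)
  up_idx <- dex_idx[seq_len(cfg$dge_n_up)]
  down_idx <- setdiff(dex_idx, up_idx)
  lfc <- pmin(0.9, pmax(-0.9, stats::rnorm(cfg$n_genes, 0, 0.3)))
  padj <- stats::runif(cfg$n_genes)
  lfc[up_idx] <- stats::runif(cfg$dge_n_up, cfg$dge_lfc, cfg$dge_lfc + 1.5)
  lfc[down_idx] <- -stats::runif(cfg$dge_n_down, cfg$dge_lfc,
                                 cfg$dge_lfc + 1.5)
  padj[dex_idx] <- stats::runif(length(dex_idx), 0, 0.01)
  dge_table <- tibble(gene_id = g$gene_id, log2fc = lfc, padj = padj)

  truth <- list(
    config = unclass(cfg),
    hub_genes = sort(hub_genes),
    distal_hub_genes = sort(distal_hub_genes),
    tr_count = stats::setNames(as.integer(tr_count), g$gene_id),
    atac_at_promoter = stats::setNames(atac_at, g$gene_id),
    gene_set = sort(gene_set),
    dex_up = sort(g$gene_id[up_idx]),
    dex_down = sort(g$gene_id[down_idx]))

  bundle <- list(genome = genome, transcripts = transcripts, genes = genes,
                 tr_peaks = tr_peaks, atac_peaks = atac_peaks,
                 histone_peaks = histone_peaks, expression = expression,
                 score_track = score_track, gene_set = sort(gene_set),
                 dge_table = dge_table, truth = truth)
  if (!is.null(dir)) write_dataset(bundle, dir)
  bundle
}

#' Null variant of the synthetic dataset
#'
#' All couplings zeroed — no hubs, no rank coupling, flat expression, no
#' hub bias in the gene set — so the null hypothesis of every enrichment
#' test holds by construction. Length biases are kept as configured (the
#' confound demonstration needs them).
#'
#' @inheritParams generate_dataset
#' @return as [generate_dataset()].
#' @export
null_dataset <- function(config, dir = NULL) {
  config$hub_fraction <- 0
  config$distal_hub_fraction <- 0
  config$pvalue_rank_coupling <- 0
  config$expr_beta_tr <- 0
  config$expr_beta_atac <- 0
  config$geneset_hub_bias <- 0
  generate_dataset(config, dir = dir)
}

#' Write a narrowPeak file (10 columns)
#'
#' @param peaks peak tibble; `score_neglog10p` goes in column 8, `NA` as the
#'   -1 sentinel.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_intervals(peaks, "write_narrowpeak input")
  p <- peaks$score_neglog10p %||% rep(NA_real_, nrow(peaks))
  pcol <- ifelse(is.na(p), "-1", format(p, scientific = FALSE, trim = TRUE))
  writeLines(paste(peaks$chrom,
                   format(peaks$start, scientific = FALSE, trim = TRUE),
                   format(peaks$end, scientific = FALSE, trim = TRUE),
                   peaks$name %||% ".", "0",
                   peaks$strand %||% ".",
                   "0", pcol, "-1", "-1", sep = "\t"), path)
  invisible(path)
}

#' Write a fixture bundle to disk in standard formats
#'
#' narrowPeak per assay, TSV tables, bedGraph conservation, and a YAML truth
#' ledger (plus a TSV of per-gene truth).
#'
#' @param bundle output of [generate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in names(bundle$tr_peaks)) {
    write_narrowpeak(bundle$tr_peaks[[tr]],
                     file.path(dir, paste0(tr, ".narrowPeak")))
  }
  write_narrowpeak(bundle$atac_peaks, file.path(dir, "ATAC.narrowPeak"))
  for (mk in names(bundle$histone_peaks)) {
    write_narrowpeak(bundle$histone_peaks[[mk]],
                     file.path(dir, paste0(mk, ".narrowPeak")))
  }
  write_tsv_table(bundle$transcripts, file.path(dir, "genes.tsv"))
  write_tsv_table(bundle$expression, file.path(dir, "expression.tsv"))
  write_tsv_table(bundle$dge_table, file.path(dir, "dge.tsv"))
  write_tsv_table(tibble(gene_id = bundle$gene_set),
                  file.path(dir, "gene_set.tsv"))
  write_tsv_table(bundle$genome, file.path(dir, "genome.tsv"))
  write_score_track(bundle$score_track,
                    file.path(dir, "conservation.bedGraph"))
  truth <- bundle$truth
  per_gene <- tibble(gene_id = names(truth$tr_count),
                     tr_count = unname(truth$tr_count),
                     atac = unname(truth$atac_at_promoter),
                     hub = names(truth$tr_count) %in% truth$hub_genes)
  write_tsv_table(per_gene, file.path(dir, "truth_per_gene.tsv"))
  yaml::write_yaml(list(config = truth$config,
                        hub_genes = truth$hub_genes,
                        distal_hub_genes = truth$distal_hub_genes,
                        gene_set = truth$gene_set,
                        dex_up = truth$dex_up,
                        dex_down = truth$dex_down),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Lightweight gene-table generator for enrichment calibration
#'
#' Draws a gene table with a binary indicator and a log-normal cDNA-length
#' covariate, plus a gene set, with independent control over how strongly
#' indicator and set membership each couple to length and whether any true
#' (beyond-length) enrichment is planted. Used by the permutation
#' calibration and confound-demonstration suites.
#'
#' @param n_genes,set_size sizes.
#' @param indicator_rate marginal indicator probability.
#' @param indicator_length_bias logit slope of the indicator on standardised
#'   log length.
#' @param set_length_bias log-weight of set sampling on standardised log
#'   length.
#' @param true_enrichment log-weight of set sampling on the indicator
#'   itself (0 = null).
#' @param seed integer seed.
#' @return list: `gene_table` (`gene_id`, `cdna_length`, `indicator`),
#'   `gene_set`.
#' @export
synthetic_gene_table <- function(n_genes = 1000, set_size = 100,
                                 indicator_rate = 0.3,
                                 indicator_length_bias = 0,
                                 set_length_bias = 0,
                                 true_enrichment = 0, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cdna <- pmax(200, round(stats::rlnorm(n_genes, log(2000), 0.6)))
  z <- as.numeric(scale(log(cdna)))
  eta <- stats::qlogis(indicator_rate) + indicator_length_bias * z
  ind <- stats::runif(n_genes) < stats::plogis(eta)
  ids <- sprintf("G%05d", seq_len(n_genes))
  w <- exp(set_length_bias * z + true_enrichment * ind)
  gene_set <- sample(ids, set_size, prob = w)
  list(gene_table = tibble(gene_id = ids, cdna_length = cdna,
                           indicator = ind),
       gene_set = sort(gene_set))
}
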