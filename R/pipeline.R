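# End-to-end orchestration: one call runs simulate -> annotate -> converge
# -> concord -> enrich -> report over a directory of standard-format inputs
# (or the bundled generator), writing versioned TSV outputs and a JSON
# manifest capturing inputs, parameters and seeds.

#' Pipeline run configuration
#'
#' @param data_dir directory of input files (narrowPeak per assay,
#'   `genes.tsv`, `expression.tsv`, `conservation.bedGraph`, `gene_set.tsv`,
#'   `dge.tsv`, `genome.tsv`); `NULL` to simulate with `synthetic`.
#' @param out_dir output directory.
#' @param synthetic a [synthetic_config()] used when `data_dir` is `NULL`.
#' @param tr_names regulator assay labels (narrowPeak file stems).
#' @param promoter_window promoter length in bp.
#' @param top_n_proximal,top_n_distal top-N cuts for concordance; `NA`
#'   selects the largest n available across assays.
#' @param link a [link_config()].
#' @param n_perm,seed permutation settings.
#' @return a `run_config` list (all defaults echoed — no hidden defaults).
#' @export
run_config <- function(data_dir = NULL, out_dir = tempfile("trconverge_run"),
                       synthetic = synthetic_config(),
                       tr_names = c("ARID1B", "BCL11A", "FOXP1", "TBR1",
                                    "TCF7L2"),
                       promoter_window = 2000,
                       top_n_proximal = NA, top_n_distal = NA,
                       link = link_config(),
                       n_perm = 999, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full convergence pipeline
#'
#' Stages: `simulate` (when no input directory is given), `annotate`
#' (promoters, proximal/distal classification), `converge` (locus table,
#' membership counts, overlap fractions, conservation), `concord` (panel
#' concordance), `enrich` (shuffle and covariate-matched permutation tests,
#' gene-set chi-squared, distal window linking, expression strata, DEX
#' filter), `report` (summary tables). Every stage writes TSV outputs under
#' `out_dir`; a `manifest.json` records inputs, parameters, seeds and the
#' package version. Reruns with the same config produce identical result
#' files.
#'
#' @param config a [run_config()] or the path of a YAML file with the same
#'   fields.
#' @return (invisibly) a list with the in-memory results:
#'   `annotation`, `locus_table`, `counts`, `concordance`, `enrichment`,
#'   `summary`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) {
    cfg_list <- yaml::read_yaml(config)
    config <- do.call(run_config, cfg_list[setdiff(names(cfg_list),
                                                   c("synthetic", "link"))])
    if (!is.null(cfg_list$synthetic)) {
      config$synthetic <- do.call(synthetic_config, cfg_list$synthetic)
    }
    if (!is.null(cfg_list$link)) {
      config$link <- do.call(link_config, cfg_list$link)
    }
  }
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character()

  ## -- load or simulate -----------------------------------------------------
  if (is.null(config$data_dir)) {
    bundle <- generate_dataset(config$synthetic)
    stages <- c(stages, "simulate")
  } else {
    bundle <- read_dataset(config$data_dir, config$tr_names)
  }
  genome <- bundle$genome
  genes <- bundle$genes

  ## -- annotate -------------------------------------------------------------
  promoters <- build_promoters(genes, config$promoter_window, genome)
  all_tr <- bind_rows(bundle$tr_peaks)
  annotated <- classify_peaks(all_tr, promoters, genes)
  write_tsv_table(annotated |> select(-"proximal_genes"),
                  file.path(out_dir, "peak_annotation.tsv"))
  stages <- c(stages, "annotate")

  ## -- converge -------------------------------------------------------------
  loci <- merge_loci(annotated, bundle$atac_peaks, bundle$histone_peaks,
                     genome_label = "synthetic")
  counts <- membership_counts(loci)
  ov_atac <- overlap_fractions(all_tr, bundle$atac_peaks)
  cons <- conservation_summary(loci |> filter(.data$tr_count == 5,
                                              .data$atac),
                               bundle$score_track)
  write_tsv_table(loci, file.path(out_dir, "locus_table.tsv"))
  write_tsv_table(counts$subsets, file.path(out_dir, "upset_counts.tsv"))
  write_bed(loci |> filter(.data$tr_count == 5, .data$atac) |>
              mutate(name = sprintf("locus_%05d", row_number())),
            file.path(out_dir, "loci_5TRa.bed"))
  stages <- c(stages, "converge")

  ## -- concord --------------------------------------------------------------
  by_assay <- split(annotated, annotated$assay)
  n_prox <- config$top_n_proximal
  if (is.na(n_prox)) {
    n_prox <- min(map_int(by_assay,
                          ~ sum(.x$class == "proximal" &
                                  !is.na(.x$score_neglog10p))))
  }
  concord <- panel_concordance(by_assay, n = n_prox, class = "proximal")
  write_tsv_table(concord, file.path(out_dir, "concordance_proximal.tsv"))
  stages <- c(stages, "concord")

  ## -- enrich ---------------------------------------------------------------
  loci5 <- loci |> filter(.data$tr_count == 5, .data$atac)
  shuffle <- shuffle_overlap_test(
    loci |> filter(.data$tr_count == 5), bundle$atac_peaks, genome,
    n_perm = config$n_perm, seed = config$seed)
  sig <- genes_with_proximal_signature(loci, promoters, min_tr_count = 5,
                                       require_atac = TRUE,
                                       gene_set = bundle$gene_set)
  gene_tbl <- genes |>
    mutate(indicator = .data$gene_id %in% sig$genes)
  perm <- geneset_permutation_enrich(gene_tbl, bundle$gene_set,
                                     n_perm = config$n_perm,
                                     seed = config$seed)
  in_set <- gene_tbl$gene_id %in% bundle$gene_set
  chi <- contingency_test(sum(gene_tbl$indicator & in_set),
                          sum(!gene_tbl$indicator & in_set),
                          sum(gene_tbl$indicator & !in_set),
                          sum(!gene_tbl$indicator & !in_set))
  links <- link_distal_to_genes(loci, genes, config$link, bundle$gene_set)
  profile <- gene_binding_profile(genes, promoters, loci, config$link)
  strata <- expression_stratify(profile, bundle$expression)
  dex <- dex_filter(bundle$dge_table)
  write_tsv_table(tidy(shuffle), file.path(out_dir, "shuffle_test.tsv"))
  write_tsv_table(tidy(perm), file.path(out_dir, "geneset_perm.tsv"))
  write_tsv_table(links$summary, file.path(out_dir, "distal_links.tsv"))
  write_tsv_table(strata$by_tr_count,
                  file.path(out_dir, "expression_by_tr_count.tsv"))
  stages <- c(stages, "enrich")

  ## -- report ---------------------------------------------------------------
  summary_tbl <- tibble(
    quantity = c("n_loci", "n_proximal_loci", "pct_proximal_5tr",
                 "pct_5tr_with_atac", "pct_singletr_with_atac",
                 "pct_geneset_proximal_signature",
                 sprintf("pct_geneset_linked_%dkb",
                         config$link$windows_bp / 1000),
                 "conservation_fraction_above", "mean_rho",
                 "shuffle_p", "geneset_perm_p", "chi2"),
    value = c(nrow(loci), sum(loci$class == "proximal"),
              pct_5tr_of_class(counts, "proximal"),
              pct_atac_at(counts, "proximal", 5),
              pct_atac_at(counts, "proximal", 1),
              sig$summary$pct_linked,
              links$summary$pct_set_linked,
              cons$summary$fraction_above,
              mean(concord$rho, na.rm = TRUE),
              shuffle$p_empirical, perm$p_empirical, chi$chi2))
  write_tsv_table(summary_tbl, file.path(out_dir, "summary.tsv"))
  stages <- c(stages, "report")

  manifest <- list(
    package = "trconverge",
    version = as.character(utils::packageVersion("trconverge")),
    stages = stages,
    data_dir = config$data_dir %||% "simulated",
    parameters = list(
      promoter_window = config$promoter_window,
      top_n_proximal = n_prox,
      link_windows_bp = config$link$windows_bp,
      link_min_tr_count = config$link$min_tr_count,
      n_perm = config$n_perm),
    seeds = list(pipeline = config$seed,
                 synthetic = if (is.null(config$data_dir))
                   config$synthetic$seed else NULL))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(annotation = annotated, locus_table = loci,
                 counts = counts, overlap_atac = ov_atac,
                 conservation = cons, concordance = concord,
                 enrichment = list(shuffle = shuffle, geneset_perm = perm,
                                   chi2 = chi, links = links,
                                   strata = strata, dex = dex),
                 summary = summary_tbl, out_dir = out_dir))
}

#' @noRd
pct_5tr_of_class <- function(counts, cls) {
  d <- counts$by_tr_count |> filter(.data$class == cls)
  tot <- sum(d$n)
  pct(sum(d$n[d$tr_count == 5]), tot)
}

#' @noRd
pct_atac_at <- function(counts, cls, k) {
  d <- counts$by_tr_count |>
    filter(.data$class == cls, .data$tr_count == k)
  if (nrow(d) == 0) return(NA_real_)
  d$pct_atac
}

#' Read a directory of standard-format inputs as a bundle
#'
#' Counterpart of [write_dataset()]: expects `<TR>.narrowPeak` per assay,
#' `ATAC.narrowPeak`, optional `H3K27ac.narrowPeak`/`H3K27me3.narrowPeak`,
#' `genes.tsv`, `expression.tsv`, `dge.tsv`, `gene_set.tsv`, `genome.tsv`,
#' `conservation.bedGraph`.
#'
#' @param dir input directory.
#' @param tr_names regulator file stems.
#' @return a bundle list as produced by [generate_dataset()] (no `truth`).
#' @export
read_dataset <- function(dir, tr_names) {
  need <- file.path(dir, c(paste0(tr_names, ".narrowPeak"),
                           "ATAC.narrowPeak", "genes.tsv", "genome.tsv"))
  missing_files <- need[!file.exists(need)]
  if (length(missing_files) > 0) {
    abort(sprintf("missing input file: %s", missing_files[1]))
  }
  tr_peaks <- stats::setNames(
    map(tr_names, ~ read_narrowpeak(file.path(dir, paste0(.x, ".narrowPeak")),
                                    assay = .x)),
    tr_names)
  histone <- list()
  for (mk in c("H3K27ac", "H3K27me3")) {
    f <- file.path(dir, paste0(mk, ".narrowPeak"))
    if (file.exists(f)) histone[[mk]] <- read_narrowpeak(f, assay = mk)
  }
  gen_tbl <- readr::read_tsv(file.path(dir, "genome.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  opt_tsv <- function(name) {
    f <- file.path(dir, name)
    if (file.exists(f)) readr::read_tsv(f, show_col_types = FALSE,
                                        progress = FALSE) else NULL
  }
  transcripts <- read_gene_table(file.path(dir, "genes.tsv"))
  cons_f <- file.path(dir, "conservation.bedGraph")
  gs <- opt_tsv("gene_set.tsv")
  list(genome = genome_def(gen_tbl$chrom, gen_tbl$length),
       transcripts = transcripts,
       genes = gene_models(transcripts),
       tr_peaks = tr_peaks,
       atac_peaks = read_narrowpeak(file.path(dir, "ATAC.narrowPeak"),
                                    assay = "ATAC"),
       histone_peaks = histone,
       expression = opt_tsv("expression.tsv"),
       score_track = if (file.exists(cons_f)) read_score_track(cons_f)
       else NULL,
       gene_set = if (!is.null(gs)) gs$gene_id else NULL,
       dge_table = opt_tsv("dge.tsv"))
}
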