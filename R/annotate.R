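# Promoter construction and proximal/distal peak classification.
#
# "Upstream" is strand-aware and excludes the TSS base itself: the promoter
# window is the window_bp bases immediately 5' of the first transcribed base.
# For a + strand TSS t that is [t - window_bp, t); for a - strand TSS t it is
# [t + 1, t + 1 + window_bp) (the first transcribed base t is excluded, and
# upstream runs toward larger coordinates).

#' Build strand-aware promoter windows per gene
#'
#' Each transcript TSS contributes a window of `window_bp` bases immediately
#' upstream (5') of the TSS, excluding the TSS base itself. Windows of the
#' same gene are merged (union); windows are clipped to chromosome bounds.
#' Promoters of different genes are kept separate and may overlap each other.
#'
#' @param genes per-gene tibble from [gene_models()].
#' @param window_bp promoter window length in bp (default 2000).
#' @param genome [genome_def()] tibble used for clipping; `NULL` skips the
#'   upper-bound clip (lower bound 0 is always enforced).
#' @return tibble `gene_id`, `chrom`, `strand`, `start`, `end` with one row
#'   per merged promoter interval; attribute `window_bp` records the window.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
#'                     tss_list = list(10000L), cdna_length = 1500,
#'                     biotype = "protein_coding")
#' build_promoters(g, 2000)  # [8000, 10000)
#' @export
build_promoters <- function(genes, window_bp = 2000, genome = NULL) {
  if (window_bp <= 0) abort("window_bp must be > 0")
  tss_tbl <- genes |>
    select("gene_id", "chrom", "strand", "tss_list") |>
    tidyr::unnest(cols = "tss_list") |>
    rename(tss = "tss_list")
  if (!is.null(genome)) {
    m <- match(tss_tbl$chrom, genome$chrom)
    if (anyNA(m)) abort("gene chromosome absent from genome")
    if (any(tss_tbl$tss >= genome$length[m] | tss_tbl$tss < 0)) {
      abort("TSS outside chromosome bounds")
    }
  }
  win <- tss_tbl |>
    mutate(
      start = ifelse(.data$strand == "+", .data$tss - window_bp,
                     .data$tss + 1),
      end = ifelse(.data$strand == "+", .data$tss,
                   .data$tss + 1 + window_bp)
    ) |>
    mutate(start = pmax(.data$start, 0))
  if (!is.null(genome)) {
    m <- match(win$chrom, genome$chrom)
    win$end <- pmin(win$end, genome$length[m])
  }
  win <- win |> filter(.data$start < .data$end)
  # per-gene union of windows
  out <- win |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }) |>
    ungroup() |>
    arrange(.data$gene_id, .data$start)
  attr(out, "window_bp") <- window_bp
  out
}

# Unsigned distance from a half-open peak [start, end) to a TSS position:
# 0 when the TSS lies inside the peak, else distance from the nearest
# included base (start or end - 1) to the TSS.
#' @noRd
edge_tss_distance <- function(start, end, tss) {
  ifelse(tss >= start & tss < end, 0,
         ifelse(tss >= end, tss - (end - 1), start - tss))
}

#' Classify peaks as proximal or distal with gene assignment
#'
#' A peak with at least 1 bp of overlap with any promoter window is
#' *proximal* and credits every overlapped gene. Any other peak is *distal*
#' and is assigned the nearest TSS across all transcripts of all genes
#' (protein-coding and non-coding alike, strand-agnostic), with the unsigned
#' edge-to-TSS distance. Equidistant TSSs are resolved to the
#' lexicographically smallest `gene_id`.
#'
#' @param peaks peak tibble (`chrom`, `start`, `end`, ...).
#' @param promoters promoter tibble from [build_promoters()].
#' @param genes per-gene tibble from [gene_models()].
#' @return input peaks plus columns `class` (`"proximal"`/`"distal"`),
#'   `proximal_genes` (list-column of gene ids; empty for distal),
#'   `distal_gene` (`NA` for proximal or unassignable peaks) and
#'   `distance_bp` (`NA` for proximal).
#' @export
classify_peaks <- function(peaks, promoters, genes) {
  validate_intervals(peaks, "peaks")
  n <- nrow(peaks)
  if (n == 0) {
    return(peaks |> mutate(class = character(), proximal_genes = list(),
                           distal_gene = character(), distance_bp = double()))
  }
  pk_gr <- as_granges(peaks |> select("chrom", "start", "end"))
  prom_gr <- as_granges(promoters |> select("chrom", "start", "end"))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pk_gr, prom_gr, ignore.strand = TRUE))
  prox_genes <- vector("list", n)
  for (i in seq_len(n)) prox_genes[[i]] <- character()
  if (length(hits) > 0) {
    hit_tbl <- tibble(peak = S4Vectors::queryHits(hits),
                      gene_id = promoters$gene_id[S4Vectors::subjectHits(hits)]) |>
      distinct()
    split_genes <- split(hit_tbl$gene_id, hit_tbl$peak)
    idx <- as.integer(names(split_genes))
    prox_genes[idx] <- map(split_genes, ~ sort(unique(.x)))
  }
  is_prox <- lengths(prox_genes) > 0

  tss_tbl <- genes |>
    select("gene_id", "chrom", "tss_list") |>
    tidyr::unnest(cols = "tss_list") |>
    rename(tss = "tss_list") |>
    arrange(.data$chrom, .data$tss, .data$gene_id)

  distal_gene <- rep(NA_character_, n)
  distance_bp <- rep(NA_real_, n)
  distal_idx <- which(!is_prox)
  if (length(distal_idx) > 0 && nrow(tss_tbl) > 0) {
    tss_by_chrom <- split(tss_tbl, tss_tbl$chrom)
    for (i in distal_idx) {
      td <- tss_by_chrom[[peaks$chrom[i]]]
      if (is.null(td)) next  # chromosome absent from gene table: flagged NA
      d <- edge_tss_distance(peaks$start[i], peaks$end[i], td$tss)
      best <- min(d)
      cand <- td$gene_id[d == best]
      distal_gene[i] <- min(cand)  # lexicographic tie-break
      distance_bp[i] <- best
    }
  }
  peaks |>
    mutate(class = ifelse(is_prox, "proximal", "distal"),
           proximal_genes = prox_genes,
           distal_gene = distal_gene,
           distance_bp = distance_bp)
}

#' Genes carrying a qualifying proximal binding signature
#'
#' A gene qualifies when at least one *proximal* locus overlapping its
#' promoter has at least `min_tr_count` regulator members (and an
#' open-chromatin peak, when `require_atac`). Typical use: the five-TR +
#' ATAC ("5TRa") promoter signature, `min_tr_count = 5, require_atac = TRUE`.
#'
#' @param locus_table locus tibble from [merge_loci()].
#' @param promoters promoter tibble from [build_promoters()].
#' @param min_tr_count minimum number of regulator assays at the locus.
#' @param require_atac require the locus ATAC flag.
#' @param gene_set optional character vector of gene ids; when supplied the
#'   summary reports the count and percentage of the set qualifying.
#' @return list with `genes` (character vector of qualifying gene ids) and
#'   `summary` (one-row tibble; see [linked_gene_summary()]) when `gene_set`
#'   is given.
#' @export
genes_with_proximal_signature <- function(locus_table, promoters,
                                          min_tr_count = 5,
                                          require_atac = TRUE,
                                          gene_set = NULL) {
  if (!is.null(gene_set) && length(gene_set) == 0) abort("gene_set is empty")
  qual <- locus_table |>
    filter(.data$class == "proximal", .data$tr_count >= min_tr_count)
  if (require_atac) qual <- qual |> filter(.data$atac)
  genes <- character()
  if (nrow(qual) > 0 && nrow(promoters) > 0) {
    hits <- GenomicRanges::findOverlaps(
      as_granges(qual |> select("chrom", "start", "end")),
      as_granges(promoters |> select("chrom", "start", "end")),
      ignore.strand = TRUE)
    genes <- sort(unique(promoters$gene_id[S4Vectors::subjectHits(hits)]))
  }
  out <- list(genes = genes)
  if (!is.null(gene_set)) out$summary <- linked_gene_summary(genes, gene_set)
  out
}
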