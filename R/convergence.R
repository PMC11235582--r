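# Independent loci: single-linkage merge of regulator peaks across assays,
# per-assay membership flags, and summaries over the resulting locus table.

#' Merge regulator peaks into independent loci with membership flags
#'
#' Overlapping regulator (TR) peaks are merged transitively (single linkage,
#' >= 1 bp overlap; bookended intervals do not merge) into maximal
#' "independent loci". Each locus records which TR assays overlap it
#' (`membership`, `tr_count`), whether any open-chromatin peak overlaps it
#' (`atac`), optional histone-mark flags, and its class: proximal when any
#' constituent TR peak is proximal, distal otherwise.
#'
#' ATAC and histone peaks only flag loci; they do not extend the merge.
#'
#' @param tr_peaks tibble of TR peaks with an `assay` column, annotated by
#'   [classify_peaks()] (needs `class`); concatenate assays with
#'   `dplyr::bind_rows()`.
#' @param atac_peaks optional interval tibble of open-chromatin peaks.
#' @param histone_peaks optional named list of interval tibbles
#'   (e.g., `list(H3K27ac = ..., H3K27me3 = ...)`).
#' @param genome_label optional label; stored and checked by cross-dataset
#'   operations.
#' @return locus tibble: `chrom`, `start`, `end`, `class`, `membership`
#'   (list-column of assay labels), `tr_count`, `atac`, one logical column
#'   per histone mark; attribute `genome`.
#' @export
merge_loci <- function(tr_peaks, atac_peaks = NULL, histone_peaks = NULL,
                       genome_label = NA_character_) {
  validate_intervals(tr_peaks, "tr_peaks")
  if (!"assay" %in% names(tr_peaks)) abort("tr_peaks needs an assay column")
  if (!"class" %in% names(tr_peaks)) {
    abort("tr_peaks must be annotated first (classify_peaks)")
  }
  if (nrow(tr_peaks) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  class = character(), membership = list(),
                  tr_count = integer(), atac = logical())
    attr(out, "genome") <- genome_label
    return(out)
  }
  pk_gr <- as_granges(tr_peaks |> select("chrom", "start", "end"))
  # min.gapwidth = 0: bookended peaks (end == start) must NOT merge
  loci_gr <- GenomicRanges::reduce(pk_gr, ignore.strand = TRUE,
                                   min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(pk_gr, loci_gr, ignore.strand = TRUE)
  # reduce() guarantees each peak lands in exactly one merged locus
  locus_of_peak <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
  per_locus <- tibble(locus = locus_of_peak,
                      assay = tr_peaks$assay,
                      class = tr_peaks$class) |>
    group_by(.data$locus) |>
    summarise(membership = list(sort(unique(.data$assay))),
              class = ifelse(any(.data$class == "proximal"),
                             "proximal", "distal"),
              .groups = "drop") |>
    arrange(.data$locus)
  stopifnot(nrow(per_locus) == length(loci_gr))
  out <- granges_to_tbl(loci_gr) |>
    mutate(class = per_locus$class,
           membership = per_locus$membership,
           tr_count = lengths(per_locus$membership))
  flag_overlap <- function(flag_peaks) {
    if (is.null(flag_peaks) || nrow(flag_peaks) == 0) {
      return(rep(FALSE, nrow(out)))
    }
    GenomicRanges::countOverlaps(
      loci_gr, as_granges(flag_peaks |> select("chrom", "start", "end")),
      ignore.strand = TRUE) > 0
  }
  out$atac <- flag_overlap(atac_peaks)
  for (mark in names(histone_peaks)) {
    out[[mark]] <- flag_overlap(histone_peaks[[mark]])
  }
  attr(out, "genome") <- genome_label
  out
}

#' UpSet-style membership counts for a locus table
#'
#' Tabulates loci by (membership subset x ATAC flag) and by TR count, with
#' percentages of the class total — the numbers behind combinatorial
#' co-binding plots such as "99.0% of five-TR proximal loci have concurrent
#' open chromatin".
#'
#' @param locus_table tibble from [merge_loci()].
#' @param by_class tabulate within each proximal/distal class (default TRUE).
#' @return list of tibbles: `subsets` (one row per membership combination x
#'   atac), `by_tr_count` (marginal over the number of TRs, with
#'   `n_atac` and `pct_atac`), and `class_totals`.
#' @export
membership_counts <- function(locus_table, by_class = TRUE) {
  grp <- if (by_class) "class" else character()
  base <- locus_table |>
    mutate(membership_key = map_chr(.data$membership, paste, collapse = "+"))
  class_totals <- base |>
    group_by(across(all_of(grp))) |>
    summarise(n_loci = n(), .groups = "drop")
  add_totals <- function(d) {
    if (length(grp) == 0) mutate(d, n_loci = nrow(base))
    else left_join(d, class_totals, by = grp)
  }
  subsets <- base |>
    group_by(across(all_of(c(grp, "membership_key", "atac")))) |>
    summarise(n = n(), tr_count = .data$tr_count[1], .groups = "drop") |>
    add_totals() |>
    mutate(pct_of_class = pct(.data$n, .data$n_loci)) |>
    select(-"n_loci") |>
    arrange(desc(.data$tr_count), .data$membership_key, desc(.data$atac))
  by_tr_count <- base |>
    group_by(across(all_of(c(grp, "tr_count")))) |>
    summarise(n = n(), n_atac = sum(.data$atac), .groups = "drop") |>
    add_totals() |>
    mutate(pct_of_class = pct(.data$n, .data$n_loci),
           pct_atac = pct(.data$n_atac, .data$n)) |>
    select(-"n_loci") |>
    arrange(across(all_of(grp)), desc(.data$tr_count))
  list(subsets = subsets, by_tr_count = by_tr_count,
       class_totals = class_totals)
}

#' Peak-level and nucleotide-level overlap fractions
#'
#' `peak_fraction`: percentage of query peaks with >= 1 bp overlap of any
#' target interval. `nucleotide_fraction`: percentage of the merged query
#' coverage (bp) that lies inside the target.
#'
#' @param query,target interval tibbles on the same genome.
#' @return one-row tibble `n_query`, `peak_fraction`, `nucleotide_fraction`
#'   (both in `[0, 100]`).
#' @export
overlap_fractions <- function(query, target) {
  validate_intervals(query, "query")
  validate_intervals(target, "target")
  if (nrow(query) == 0) abort("empty query")
  q_gr <- as_granges(query |> select("chrom", "start", "end"))
  t_gr <- as_granges(target |> select("chrom", "start", "end"))
  n_hit <- sum(GenomicRanges::countOverlaps(q_gr, t_gr,
                                            ignore.strand = TRUE) > 0)
  q_cov <- GenomicRanges::reduce(q_gr, ignore.strand = TRUE)
  t_cov <- GenomicRanges::reduce(t_gr, ignore.strand = TRUE)
  inter <- GenomicRanges::intersect(q_cov, t_cov, ignore.strand = TRUE)
  tibble(
    n_query = nrow(query),
    peak_fraction = pct(n_hit, nrow(query)),
    nucleotide_fraction = pct(sum(GenomicRanges::width(inter)),
                              sum(GenomicRanges::width(q_cov)))
  )
}

#' Per-locus maximum conservation score and threshold summary
#'
#' For each locus, the maximum score over all overlapping track intervals
#' (0 where the track has no coverage: conservation tracks omit unalignable,
#' unconserved bases). Reports the fraction of loci whose maximum exceeds
#' the threshold.
#'
#' @param locus_table tibble of loci.
#' @param score_track tibble `chrom`, `start`, `end`, `value` with values in
#'   `[0, 1]` (see [read_score_track()]).
#' @param threshold conservation threshold in `[0, 1]` (default 0.5).
#' @return list: `per_locus` (locus table plus `max_score`, `above`),
#'   `summary` (one-row tibble `n_loci`, `n_above`, `fraction_above` as %,
#'   `threshold`).
#' @export
conservation_summary <- function(locus_table, score_track, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) abort("threshold outside [0,1]")
  validate_score_track(score_track)
  max_score <- rep(0, nrow(locus_table))
  if (nrow(locus_table) > 0 && nrow(score_track) > 0) {
    hits <- GenomicRanges::findOverlaps(
      as_granges(locus_table |> select("chrom", "start", "end")),
      as_granges(score_track |> select("chrom", "start", "end")),
      ignore.strand = TRUE)
    if (length(hits) > 0) {
      mx <- tapply(score_track$value[S4Vectors::subjectHits(hits)],
                   S4Vectors::queryHits(hits), max)
      max_score[as.integer(names(mx))] <- as.numeric(mx)
    }
  }
  per_locus <- locus_table |>
    mutate(max_score = max_score, above = max_score > threshold)
  list(per_locus = per_locus,
       summary = tibble(n_loci = nrow(per_locus),
                        n_above = sum(per_locus$above),
                        fraction_above = pct(sum(per_locus$above),
                                             nrow(per_locus)),
                        threshold = threshold))
}

#' Configuration for distal locus-to-gene window linking
#'
#' @param windows_bp ascending window sizes in bp (defaults 100 kb, 500 kb).
#' @param min_tr_count minimum TR membership of a qualifying distal locus.
#' @param required_assays assay labels that must all be present (default the
#'   ARID1B + BCL11A + TBR1 trio); `NULL` to require only `min_tr_count`.
#' @param require_atac qualifying loci must carry the ATAC flag.
#' @return a `link_config` list.
#' @export
link_config <- function(windows_bp = c(100000, 500000), min_tr_count = 3,
                        required_assays = c("ARID1B", "BCL11A", "TBR1"),
                        require_atac = TRUE) {
  if (is.unsorted(windows_bp)) abort("windows_bp must be ascending")
  structure(list(windows_bp = windows_bp, min_tr_count = min_tr_count,
                 required_assays = required_assays,
                 require_atac = require_atac),
            class = "link_config")
}

#' Link qualifying distal loci to genes within distance windows
#'
#' A gene is linked at window `w` when any qualifying distal locus (class
#' distal, membership containing all `required_assays`, `tr_count >=
#' min_tr_count`, ATAC flag if required) lies within `w` bp of any of its
#' TSSs (unsigned edge-to-TSS distance; overlap counts as 0).
#'
#' @param locus_table tibble from [merge_loci()].
#' @param genes per-gene tibble from [gene_models()].
#' @param config a [link_config()].
#' @param gene_set optional gene ids to summarise against (non-empty).
#' @return list: `linked` (tibble `window_bp`, `gene_id`), `summary` (per
#'   window: `n_linked`, and within `gene_set` when given: `n_set`,
#'   `n_set_linked`, `pct_set_linked`).
#' @export
link_distal_to_genes <- function(locus_table, genes, config = link_config(),
                                 gene_set = NULL) {
  if (!is.null(gene_set) && length(gene_set) == 0) abort("gene_set is empty")
  qual <- locus_table |>
    filter(.data$class == "distal", .data$tr_count >= config$min_tr_count)
  if (config$require_atac) qual <- qual |> filter(.data$atac)
  if (!is.null(config$required_assays)) {
    qual <- qual |>
      filter(map_lgl(.data$membership,
                     ~ all(config$required_assays %in% .x)))
  }
  tss_tbl <- genes |>
    select("gene_id", "chrom", "tss_list") |>
    tidyr::unnest(cols = "tss_list") |>
    rename(tss = "tss_list")
  linked <- map(config$windows_bp, function(w) {
    if (nrow(qual) == 0 || nrow(tss_tbl) == 0) return(character())
    # a locus within w of a TSS <=> the TSS falls in the locus dilated by w
    dil <- qual |>
      mutate(start = pmax(.data$start - w, 0), end = .data$end + w)
    hits <- GenomicRanges::findOverlaps(
      as_granges(tss_tbl |>
                   mutate(start = .data$tss, end = .data$tss + 1) |>
                   select("chrom", "start", "end")),
      as_granges(dil |> select("chrom", "start", "end")),
      ignore.strand = TRUE)
    sort(unique(tss_tbl$gene_id[S4Vectors::queryHits(hits)]))
  })
  linked_tbl <- tibble(window_bp = rep(config$windows_bp, lengths(linked)),
                       gene_id = unlist(linked) %||% character())
  summary <- tibble(window_bp = config$windows_bp,
                    n_qualifying_loci = nrow(qual),
                    n_linked = lengths(linked))
  if (!is.null(gene_set)) {
    gene_set <- unique(gene_set)
    summary <- summary |>
      mutate(n_set = length(gene_set),
             n_set_linked = map_int(linked,
                                    ~ sum(gene_set %in% .x)),
             pct_set_linked = pct(.data$n_set_linked, length(gene_set)))
  }
  list(linked = linked_tbl, summary = summary)
}

# dilation logic above relies on edge-to-TSS distance: TSS inside the locus
# gives 0; outside, distance from nearest included base. Dilating the locus
# by w and testing point containment is equivalent for distance <= w.

#' Fraction of loci in one table matched by loci of another
#'
#' Both tables must be declared in the same coordinate space (pre-mapped
#' coordinates; cross-species lifting is out of scope here).
#'
#' @param locus_table_a,locus_table_b locus tibbles with `genome` attributes.
#' @return one-row tibble `n_a`, `n_matched`, `pct_matched`.
#' @export
cross_dataset_locus_match <- function(locus_table_a, locus_table_b) {
  ga <- attr(locus_table_a, "genome")
  gb <- attr(locus_table_b, "genome")
  if (!is.null(ga) && !is.null(gb) && !is.na(ga) && !is.na(gb) &&
      !identical(ga, gb)) {
    abort(sprintf("coordinate spaces differ: %s vs %s", ga, gb))
  }
  if (nrow(locus_table_a) == 0) abort("locus_table_a is empty")
  n_hit <- sum(GenomicRanges::countOverlaps(
    as_granges(locus_table_a |> select("chrom", "start", "end")),
    as_granges(locus_table_b |> select("chrom", "start", "end")),
    ignore.strand = TRUE) > 0)
  tibble(n_a = nrow(locus_table_a), n_matched = n_hit,
         pct_matched = pct(n_hit, nrow(locus_table_a)))
}
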