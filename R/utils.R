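#' @importFrom rlang .data abort warn `%||%`
#' @import dplyr
#' @importFrom tibble tibble as_tibble new_tibble
#' @importFrom purrr map map_dbl map_int map_chr map_lgl map2 map2_dbl pmap imap list_rbind
NULL

# Internal convention: all coordinates are 0-based half-open ([start, end)),
# the BED convention. GRanges is 1-based closed, so conversion happens in
# exactly two places: as_granges() and granges_to_tbl().

#' Convert an interval tibble to a GRanges object
#'
#' @param x tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `strand`; all other columns become metadata columns.
#' @return a `GenomicRanges::GRanges` (1-based closed coordinates).
#' @keywords internal
#' @noRd
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    ifelse(x$strand %in% c("+", "-"), x$strand, "*")
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
  meta <- x[setdiff(names(x), c("chrom", "start", "end", "strand"))]
  if (ncol(meta) > 0) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(meta)
  gr
}

#' @noRd
granges_to_tbl <- function(gr) {
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (ncol(meta) > 0) out <- bind_cols(out, as_tibble(meta))
  out
}

#' Validate an interval tibble
#'
#' Checks the interval invariants shared by every peak/locus table in the
#' package: non-empty chromosome names, integer-like coordinates with
#' `0 <= start < end`, and (when present) non-negative `score_neglog10p`.
#'
#' @param x a data frame with `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x` invisibly, as a tibble.
#' @export
validate_intervals <- function(x, what = "interval table") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s lacks column(s): %s", what,
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("%s: empty chromosome name", what))
  }
  if (any(x$start < 0)) abort(sprintf("%s: negative start", what))
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("%s: start >= end at row %d (%s:%d-%d)", what, bad[1],
                  x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if ("score_neglog10p" %in% names(x)) {
    sc <- x$score_neglog10p
    if (any(sc < 0, na.rm = TRUE)) {
      abort(sprintf("%s: negative score_neglog10p", what))
    }
  }
  invisible(x)
}

#' Define a genome as a table of chromosome sizes
#'
#' @param chrom character vector of chromosome names.
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return tibble with columns `chrom`, `length`.
#' @examples
#' genome_def(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_def <- function(chrom, length) {
  if (length(chrom) != length(length)) abort("chrom and length differ in length")
  if (anyDuplicated(chrom)) abort("duplicate chromosome names")
  if (any(length <= 0)) abort("chromosome lengths must be > 0")
  tibble(chrom = as.character(chrom), length = as.double(length))
}

#' @noRd
check_genome_fit <- function(x, genome, what = "intervals") {
  if (nrow(x) == 0) return(invisible(x))
  m <- match(x$chrom, genome$chrom)
  if (anyNA(m)) {
    abort(sprintf("%s: chromosome %s absent from genome", what,
                  x$chrom[which(is.na(m))[1]]))
  }
  if (any(x$end > genome$length[m])) {
    abort(sprintf("%s: interval exceeds chromosome length", what))
  }
  invisible(x)
}

# Percentage helper used by every reporting surface; one rounding rule
# everywhere (one decimal, as printed summaries in this field usually are).
#' @noRd
pct <- function(num, den) {
  out <- 100 * num / den
  out[rep_len(den <= 0, length(out))] <- NA_real_
  out
}

#' Summarise membership of a gene set among linked/qualifying genes
#'
#' Counts how many genes of `gene_set` appear in `linked_genes` and expresses
#' the count as a percentage of the set. Used for promoter-signature
#' summaries, distal window linking, and externally supplied link tables
#' (e.g., activity-by-contact enhancer-gene links).
#'
#' @param linked_genes character vector of qualifying gene ids.
#' @param gene_set character vector of gene ids of interest (non-empty).
#' @return one-row tibble: `n_set`, `n_linked`, `pct_linked`.
#' @export
linked_gene_summary <- function(linked_genes, gene_set) {
  if (length(gene_set) == 0) abort("gene_set is empty")
  gene_set <- unique(gene_set)
  n_linked <- sum(gene_set %in% linked_genes)
  tibble(
    n_set = length(gene_set),
    n_linked = n_linked,
    pct_linked = pct(n_linked, length(gene_set))
  )
}
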