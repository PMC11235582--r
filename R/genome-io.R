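# Readers/writers for the BED-family formats the pipeline touches. All
# tab-separated, headerless for BED-family, header row required for TSV
# tables. Coordinates stay 0-based half-open verbatim.

#' Read an ENCODE narrowPeak (or BED6+) file as a peak tibble
#'
#' narrowPeak is the 10-column BED extension written by MACS2: chrom, start,
#' end, name, score, strand, signalValue, pValue (-log10), qValue (-log10),
#' summit offset. Column 8 is mapped to `score_neglog10p`. The MACS2 sentinel
#' value -1 (p-value unavailable) becomes `NA`; such peaks take part in all
#' overlap computation but are excluded from rank-based operations.
#'
#' @param path file path.
#' @param assay assay label attached to every peak (e.g., `"TBR1"`,
#'   `"ATAC"`); defaults to the file name without extension.
#' @param genome_label optional genome tag recorded in the `genome` attribute.
#' @return tibble with columns `chrom`, `start`, `end`, `name`, `strand`,
#'   `score_neglog10p`, `assay`.
#' @examples
#' tf <- tempfile(fileext = ".narrowPeak")
#' writeLines("chr1\t100\t200\tp1\t0\t.\t5.0\t3.2\t2.5\t50", tf)
#' read_narrowpeak(tf, assay = "TBR1")
#' @export
read_narrowpeak <- function(path, assay = NULL,
                            genome_label = NA_character_) {
  assay <- assay %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), strand = character(),
                  score_neglog10p = double(), assay = character())
    attr(out, "genome") <- genome_label
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    abort(sprintf("malformed narrowPeak/BED line %d: fewer than 3 fields",
                  which(ncols < 3)[1]))
  }
  get <- function(i, default = NA_character_) {
    map_chr(fields, function(f) if (length(f) >= i) f[[i]] else default)
  }
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("malformed coordinate at line %d",
                  which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    abort(sprintf("invalid interval at line %d: start %d, end %d",
                  bad[1], start[bad[1]], end[bad[1]]))
  }
  p <- suppressWarnings(as.numeric(get(8)))
  p[!is.na(p) & p < 0] <- NA_real_  # MACS2 -1 sentinel
  strand <- get(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  nm <- get(4)
  nm[is.na(nm) | nm == "."] <- paste0(assay, "_", which(is.na(nm) | nm == "."))
  out <- tibble(chrom = get(1), start = start, end = end, name = nm,
                strand = strand, score_neglog10p = p, assay = assay)
  validate_intervals(out, basename(path))
  attr(out, "genome") <- genome_label
  out
}

#' Write intervals as BED
#'
#' Writes BED3 plus `name` and `score_neglog10p` columns when present
#' (placed in BED name/score positions). Round-trips exactly through
#' [read_bed()].
#'
#' @param intervals interval tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals, "write_bed input")
  cols <- list(intervals$chrom,
               format(intervals$start, scientific = FALSE, trim = TRUE),
               format(intervals$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(intervals)) {
    cols <- c(cols, list(intervals$name))
    if ("score_neglog10p" %in% names(intervals)) {
      sc <- intervals$score_neglog10p
      cols <- c(cols, list(ifelse(is.na(sc), "-1",
                                  format(sc, scientific = FALSE, trim = TRUE))))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a BED3/BED6 file
#'
#' @param path file path.
#' @param assay optional assay label.
#' @return interval tibble (columns as available: `chrom`, `start`, `end`,
#'   `name`, `strand`, `score_neglog10p`, `assay`).
#' @export
read_bed <- function(path, assay = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    abort(sprintf("malformed BED line %d", which(lengths(fields) < 3)[1]))
  }
  start <- as.integer(map_chr(fields, 2))
  end <- as.integer(map_chr(fields, 3))
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
  if (length(bad) > 0) abort(sprintf("invalid interval at line %d", bad[1]))
  out <- tibble(chrom = map_chr(fields, 1), start = start, end = end)
  nc <- min(lengths(fields))
  if (nc >= 4) out$name <- map_chr(fields, 4)
  if (nc >= 5) {
    sc <- suppressWarnings(as.numeric(map_chr(fields, 5)))
    sc[!is.na(sc) & sc < 0] <- NA_real_
    out$score_neglog10p <- sc
  }
  if (nc >= 6) {
    strand <- map_chr(fields, 6)
    strand[!strand %in% c("+", "-")] <- "."
    out$strand <- strand
  }
  if (!is.null(assay)) out$assay <- assay
  validate_intervals(out, basename(path))
  out
}

#' Read a bedGraph-like conservation score track
#'
#' Four tab-separated columns, no header: chrom, start, end, value. Values
#' must lie in `[0, 1]` (conservation probabilities) and intervals within a
#' chromosome must not overlap.
#'
#' @param path file path.
#' @return tibble `chrom`, `start`, `end`, `value`.
#' @export
read_score_track <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "integer", "integer",
                                        "numeric"))
  x <- as_tibble(x)
  validate_score_track(x)
}

#' @rdname read_score_track
#' @param x score-track tibble to validate.
#' @export
validate_score_track <- function(x) {
  validate_intervals(x, "score track")
  if (!"value" %in% names(x)) abort("score track lacks a value column")
  if (any(x$value < 0 | x$value > 1)) abort("score track values outside [0,1]")
  ov <- x |>
    arrange(.data$chrom, .data$start) |>
    group_by(.data$chrom) |>
    mutate(prev_end = lag(.data$end, default = -1)) |>
    ungroup()
  if (any(ov$start < ov$prev_end)) {
    abort("score track intervals overlap within a chromosome")
  }
  x
}

#' Write a bedGraph-like score track
#'
#' @param track tibble `chrom`, `start`, `end`, `value`.
#' @param path output path.
#' @export
write_score_track <- function(track, path) {
  writeLines(paste(track$chrom,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   format(track$value, scientific = FALSE, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Read a flattened gene/transcript table
#'
#' Tab-separated with a header row; required columns `gene_id`,
#' `transcript_id`, `chrom`, `strand`, `tss`, `cdna_length`, `biotype`.
#' `tss` is the 0-based position of the first transcribed base. Strand must
#' be `+` or `-`; transcript ids must be unique.
#'
#' @param path file path.
#' @return transcript-level tibble (one row per transcript).
#' @seealso [gene_models()] to aggregate per gene.
#' @export
read_gene_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_gene_table(as_tibble(x))
}

#' @rdname read_gene_table
#' @param x transcript-level tibble to validate.
#' @export
validate_gene_table <- function(x) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "tss",
            "cdna_length", "biotype")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("gene table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) == 0) return(x)
  dup <- x$transcript_id[duplicated(x$transcript_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate transcript_id: %s", dup[1]))
  }
  if (any(!x$strand %in% c("+", "-"))) {
    abort("gene table strand must be '+' or '-'")
  }
  if (any(x$cdna_length <= 0)) abort("cdna_length must be > 0")
  if (any(x$tss < 0)) abort("tss must be >= 0")
  per_gene <- x |> distinct(.data$gene_id, .data$chrom, .data$strand)
  if (anyDuplicated(per_gene$gene_id)) {
    abort("a gene_id spans multiple chromosomes or strands")
  }
  x
}

#' Aggregate a transcript table into per-gene models
#'
#' One row per gene with the union of its transcript TSS positions
#' (`tss_list`, a list-column of 0-based positions) and the gene-level cDNA
#' length taken as the maximum across transcripts (used downstream as the
#' covariate for length-matched permutation).
#'
#' @param transcripts transcript-level tibble (see [read_gene_table()]).
#' @return tibble `gene_id`, `chrom`, `strand`, `tss_list`, `cdna_length`,
#'   `biotype`.
#' @export
gene_models <- function(transcripts) {
  validate_gene_table(transcripts)
  if (nrow(transcripts) == 0) {
    return(tibble(gene_id = character(), chrom = character(),
                  strand = character(), tss_list = list(),
                  cdna_length = double(), biotype = character()))
  }
  transcripts |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(
      tss_list = list(sort(unique(.data$tss))),
      cdna_length = max(.data$cdna_length),
      biotype = .data$biotype[1],
      .groups = "drop"
    ) |>
    arrange(.data$gene_id)
}

#' Write a tibble as TSV (header row, tab-separated)
#'
#' @param x tibble.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  x[] <- lapply(x, function(col) {
    if (is.list(col)) map_chr(col, paste, collapse = ",") else col
  })
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
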