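# Independent brute-force oracles operating per base on small genomes.
# These stay deliberately naive (logical vectors over every base) so the
# interval arithmetic they check cannot share code with them.

# logical coverage vector over bases 0..L-1 (index i = base i-1)
oracle_bases <- function(starts, ends, L) {
  v <- logical(L)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) v[(starts[i] + 1):ends[i]] <- TRUE
  }
  v
}

# promoter bases of one gene: window bases immediately 5' of each TSS,
# TSS base excluded, clipped to [0, L)
oracle_promoter_bases <- function(tss_vec, strand, window, L) {
  v <- logical(L)
  for (t in tss_vec) {
    if (strand == "+") {
      lo <- max(t - window, 0); hi <- t - 1
    } else {
      lo <- t + 1; hi <- min(t + window, L - 1)
    }
    if (hi >= lo) v[(lo + 1):(hi + 1)] <- TRUE
  }
  v
}

# per-peak proximal/distal label, proximal genes, nearest-TSS assignment
oracle_classify <- function(peaks, genes_tbl, window, L) {
  prom <- lapply(seq_len(nrow(genes_tbl)), function(i) {
    oracle_promoter_bases(genes_tbl$tss_list[[i]], genes_tbl$strand[i],
                          window, L)
  })
  tss_long <- do.call(rbind, lapply(seq_len(nrow(genes_tbl)), function(i) {
    data.frame(gene_id = genes_tbl$gene_id[i],
               tss = genes_tbl$tss_list[[i]])
  }))
  out <- vector("list", nrow(peaks))
  for (j in seq_len(nrow(peaks))) {
    pb <- oracle_bases(peaks$start[j], peaks$end[j], L)
    hit <- vapply(prom, function(v) any(v & pb), logical(1))
    if (any(hit)) {
      out[[j]] <- list(class = "proximal",
                       proximal_genes = sort(genes_tbl$gene_id[hit]),
                       distal_gene = NA_character_,
                       distance = NA_real_)
    } else {
      bases <- which(pb) - 1
      d <- vapply(tss_long$tss, function(t) min(abs(bases - t)), double(1))
      best <- min(d)
      cand <- sort(tss_long$gene_id[d == best])
      out[[j]] <- list(class = "distal", proximal_genes = character(),
                       distal_gene = cand[1], distance = best)
    }
  }
  out
}

# connected components of the peak-overlap graph (edges: >= 1 shared base,
# so bookended peaks are NOT connected); returns loci sorted by start
oracle_merge <- function(peaks, L) {
  n <- nrow(peaks)
  if (n == 0) return(list())
  overlaps <- function(i, j) {
    peaks$chrom[i] == peaks$chrom[j] &&
      peaks$start[i] < peaks$end[j] && peaks$start[j] < peaks$end[i]
  }
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1
    queue <- i
    comp[i] <- cid
    while (length(queue) > 0) {
      cur <- queue[1]; queue <- queue[-1]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) && overlaps(cur, j)) {
          comp[j] <- cid
          queue <- c(queue, j)
        }
      }
    }
  }
  out <- lapply(seq_len(cid), function(k) {
    idx <- which(comp == k)
    list(start = min(peaks$start[idx]), end = max(peaks$end[idx]),
         membership = sort(unique(peaks$assay[idx])))
  })
  out[order(vapply(out, `[[`, 0, "start"))]
}

oracle_overlap_fractions <- function(query, target, L) {
  qv <- oracle_bases(query$start, query$end, L)
  tv <- oracle_bases(target$start, target$end, L)
  n_hit <- sum(vapply(seq_len(nrow(query)), function(j) {
    any(oracle_bases(query$start[j], query$end[j], L) & tv)
  }, logical(1)))
  c(peak = 100 * n_hit / nrow(query),
    nucleotide = 100 * sum(qv & tv) / sum(qv))
}

# per-locus max score: assign each base its track value, take the max over
# locus bases (0 where uncovered)
oracle_max_scores <- function(loci, track, L) {
  base_val <- numeric(L)
  for (i in seq_len(nrow(track))) {
    base_val[(track$start[i] + 1):track$end[i]] <- track$value[i]
  }
  vapply(seq_len(nrow(loci)), function(j) {
    max(c(0, base_val[(loci$start[j] + 1):loci$end[j]]))
  }, double(1))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracle_fisher2 <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c
  ks <- max(0, n1 - m2):min(m1, n1)
  probs <- dhyper(ks, m1, m2, n1)
  p_obs <- dhyper(a, m1, m2, n1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# average-rank Spearman computed from first principles
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random small-genome fixture: genes + multi-assay peaks on one chromosome
random_small_genome <- function(seed, L = 10000, n_genes = 4,
                                n_peaks = 12, window = 300) {
  set.seed(seed)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = "chrT",
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss_list = lapply(seq_len(n_genes), function(i) {
      k <- sample(1:2, 1)
      sort(sample(500:(L - 500), k))
    }),
    cdna_length = sample(500:3000, n_genes),
    biotype = "protein_coding")
  starts <- sample(0:(L - 60), n_peaks)
  lens <- sample(20:400, n_peaks, replace = TRUE)
  peaks <- tibble::tibble(
    chrom = "chrT",
    start = starts,
    end = pmin(starts + lens, L),
    name = sprintf("p%02d", seq_len(n_peaks)),
    strand = ".",
    score_neglog10p = round(runif(n_peaks, 0.5, 30), 3),
    assay = sample(c("A", "B", "C"), n_peaks, replace = TRUE))
  list(genome = trconverge::genome_def("chrT", L), genes = genes,
       peaks = peaks, window = window, L = L)
}
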