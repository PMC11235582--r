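---
title: "Methods: convergent multi-regulator binding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergent multi-regulator binding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trconverge)
```

# The model

The package analyses a panel of transcriptional regulators (TRs) profiled
by ChIP-seq in the same tissue, together with open-chromatin (ATAC-seq) and
histone-mark peak sets, to quantify *convergence*: the tendency of the
panel to bind the same regulatory loci, the association of that co-binding
with open chromatin, conservation and gene expression, and its enrichment
in a gene set of interest.

All coordinates are 0-based half-open (the BED convention) everywhere
internally; 1-based inputs must be converted at the boundary. Chromosome
names are compared by exact string match — no "chr" aliasing — so fixture
errors surface instead of being silently absorbed.

## Promoters and peak classes

A promoter window is the `window_bp` (default 2,000) bases immediately 5′
of a transcript TSS. "Upstream" is strand-aware and *excludes the TSS
base*: for a + strand TSS $t$ the window is $[t - w, t)$; for a − strand
TSS it is $[t + 1, t + 1 + w)$. This exclusive reading is consistent with
both "0–2,000 bp" and "1–2,000 bp" phrasings of the same definition and is
the one fixed here. Windows of one gene are unioned (multi-TSS genes get
merged windows, never more than $w$ bp per TSS); unions are per gene, so
promoters of different genes may overlap. Windows are clipped to
chromosome bounds.

A peak overlapping any promoter window by ≥ 1 bp is **proximal** and
credits *all* overlapped genes. Every other peak is **distal**, assigned
to the nearest TSS over all transcripts of all genes, protein-coding and
non-coding alike. Nearest-TSS search is strand-agnostic — the package's
documented choice where the convention is ambiguous. Distance is the
unsigned bp gap between the TSS and the nearest included peak base
(overlap ⇒ 0); ties resolve to the smaller distance, then the
lexicographically smaller `gene_id`. A peak on a chromosome absent from
the gene table stays distal with no gene, flagged `NA`.

## Independent loci and membership

TR peaks are merged by single linkage: any ≥ 1 bp overlap joins two peaks,
and chains merge transitively into maximal **independent loci**. Bookended
peaks (end = start) do *not* merge, matching the half-open convention and
standard interval-tool behaviour. Merging runs over all TR peaks at once;
a locus is classed proximal if *any* constituent peak is proximal (any
promoter overlap wins, consistent with the peak-level rule), distal
otherwise. ATAC and histone peaks never extend a locus — they only flag
it, again by ≥ 1 bp overlap. Membership of a locus is the set of TR assays
overlapping it; `tr_count` is its size. A "5TRa" locus has all five panel
TRs plus the ATAC flag; "≥3TRa" requires a configurable trio (default
ARID1B + BCL11A + TBR1) plus ATAC.

Summaries over the locus table follow directly: UpSet-style counts per
membership subset and per TR count with percentages of the class total;
peak-level and nucleotide-level overlap fractions (nucleotide fractions
are computed on the merged query coverage, making them invariant to how a
target is split into adjacent pieces); per-locus maximum conservation
score over overlapping track intervals, with loci lacking track coverage
scored 0 (conservation tracks omit unalignable — unconserved — bases);
and distal window linking, where a gene is linked at window $W$ if a
qualifying distal locus lies within $W$ bp of any of its TSSs
(edge-to-TSS distance, implemented by dilating loci by $W$ and testing
TSS containment — equivalent for distances ≤ $W$).

## Rank concordance

Each assay's peaks are ranked by ascending peak-caller p-value (descending
−log₁₀ p), with ties broken by genomic location (chrom, start, end), a
total deterministic order; the top $N$ are kept (an error names the counts
if fewer are available). Peaks carrying the peak-caller's −1 sentinel
("no p-value") are excluded from ranking only; they still participate in
all overlap computation. For a pair of top-$N$ lists, each peak of A is
matched to its best-overlapping peak of B (largest shared bp, ties to the
better B rank; many-to-one, so the intersection percentage cannot exceed
100). Spearman's ρ is computed over the matched pairs' *within-top-N*
ranks (1..N, average-rank ties) — whether global or within-list ranks are
used is not standardised, and within-top-N is the choice fixed and
documented here. ρ is computed once per unordered pair (A the lower
label), making the matrix symmetric by construction; intersection is
reported in both directions. Two panels of pairwise statistics are
compared by the unpaired two-sided Wilcoxon rank-sum test: exact when the
pooled sample is ≤ 25 without ties, otherwise the normal approximation
with tie-corrected variance and no continuity correction; identical
panels degenerate to p = 1.

## Permutation nulls

**Interval shuffle.** The statistic is the number of query loci
overlapping the target. The null re-places each query locus uniformly at
random on its own chromosome with its length preserved, placements
independent, overlaps among shuffled loci allowed — a null that accounts
for the number and sizes of loci but not their positions. Under this null
each locus hits the target independently with probability
$p_i = \frac{\#\{\text{valid starts touching the target}\}}{\#\{\text{valid starts}\}},$
computed exactly by interval arithmetic (the target dilated by the locus
length). Null draws are therefore sampled as independent Bernoulli
indicators rather than by materialising shuffled coordinates; the null
distribution is *identical* and the computation orders of magnitude
faster. The empirical p-value uses the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$, so p is
never 0 and its floor is $1/(n_\text{perm}+1)$. Direction is configurable
(enrichment by default). Excluded-region masking is not applied — length
preservation is the only constraint the null encodes.

**Covariate-matched gene-set permutation.** The statistic is the number
of set genes with a binary indicator (e.g., "has a proximal 5TRa locus").
Null sets draw, within each covariate quantile bin (deciles of cDNA length
by default; `n_bins` configurable), the same number of genes as the
observed set contributes to that bin, without replacement. Within a bin
the null count of indicator-true genes is exactly hypergeometric, so null
draws sum independent `rhyper` samples per bin — exactly equivalent to
permuting labels within bins, and fast. Matching on cDNA length matters
because gene length can confound both set membership and binding: the
test suite demonstrates that with a planted length coupling of 0.8 logit
units on both sides and *no* true enrichment, the unmatched test rejects
at far above nominal level while the decile-matched test stays inside the
95% calibration band.

## Contingency and downstream statistics

Pearson χ² on 2×2 tables uses the closed form
$\chi^2 = \frac{n(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)}$, df = 1, *without*
Yates continuity correction (at the large $n$ typical here the correction
is negligible; fixing it keeps results deterministic). Cells are held as
doubles because margin products overflow 32-bit integers at genome scale.
The odds ratio is $ad/bc$; any zero cell switches to the Haldane–Anscombe
+0.5 adjustment on all cells, flagged in the output, while χ² and the
two-sided Fisher exact p are always computed on raw counts. Fisher and
Wilcoxon tests call the standard stats implementations; the test suite
carries an independent hypergeometric-enumeration oracle and a rank-sum
enumeration as cross-checks.

DEX filtering is inclusive at both thresholds (|FC| ≥ 2 read as
log₂FC ≥ 1 or ≤ −1; p.adj ≤ 0.05). Expression stratification bins genes
by (proximal TR count) × (proximal ATAC) × (qualifying distal locus),
reports median/quartiles of log₂(TPM+1) and the fraction robustly
expressed (≥ 1), and fits a standard maximum-likelihood logistic model of
robust expression on the stratum indicators (Wald z). Per-tissue enhancer
enrichment excludes tissues with fewer than 50 positive elements (default)
before Fisher testing and BH correction. ΔΔCt combines multiple
housekeeping genes by arithmetic mean of their Ct, and reports
$2^{-\Delta\Delta Ct}$.

# The synthetic generator

`generate_dataset()` emulates the statistical structure the pipeline is
built to detect, with every planted quantity recorded in a truth ledger:

- a grid of genes (~5 kb spacing, jittered; 1–3 TSSs per gene within
  400 bp) on a small multi-chromosome genome;
- **hub promoters** (fraction `hub_fraction`, default 0.3) where all five
  TRs and ATAC each place one peak centred on the promoter midpoint with
  uniform ±500 bp jitter — deliberately wide so boundary code is
  exercised;
- independent per-TR binding at other promoters (rate 0.1), ATAC at rate
  0.2, uniform background peaks per TR (mostly distal), and shared distal
  co-bound sites (trio + ATAC) 5–80 kb from a fraction of genes;
- log-normal peak lengths, median ~600 bp with σ_log = 0.35 — a realistic
  width for transcription-factor narrow-peak calls, and wide enough that
  independently jittered co-bound peaks chain into a single locus rather
  than fragmenting;
- p-value scores at hubs formed from a shared latent ranking mixed with
  noise (`pvalue_rank_coupling`), giving tunable cross-TR rank
  concordance; background scores independent;
- expression log₂(TPM+1) = β₀ + β_TR·(TR count) + β_ATAC·ATAC + N(0, σ),
  floored at 0 (defaults 0.3, 0.5, 0.5, 0.5);
- a conservation track elevated at hub promoters (0.55–0.95 vs
  0.05–0.45);
- a gene set sampled with log-weights for hub status and/or standardised
  log cDNA length (the planted confound), and a DGE table whose planted
  up/down genes are exactly recoverable by the DEX filter.

`null_dataset()` zeroes every coupling (no hubs, no rank coupling, flat
expression, no hub bias) so each test's null holds by construction;
length biases are kept as configured for the confound demonstration.
`synthetic_gene_table()` is a lightweight gene-table-only generator used
by the calibration suites. Identical seeds give byte-identical fixture
files, and generation never disturbs the caller's RNG stream.

What the generator does *not* emulate: sequence content and motifs,
read-level noise, replicate structure and irreproducible peaks, copy
number or mappability artefacts, distance-dependent chromatin contact,
and realistic chromosome-scale clustering of genes. Passing tests
therefore show correctness of the interval arithmetic, statistics and
recovery behaviour under the stated generative model — not robustness to
every artefact of real ChIP-seq data.

# Numerical and design choices

- Peaks whose p-value carries the caller's −1 sentinel are excluded from
  rank-based operations only (how such ties were treated upstream is not
  standardised; this is the package's fixed choice).
- Locus merging runs across proximal and distal peaks together, with the
  proximal-wins class rule; merging strictly within class would make the
  mixed case unreachable and is not what the peak-level definition
  implies.
- Gene-level cDNA length aggregates transcripts by the maximum.
- `genes_with_proximal_signature()` takes the promoter map (not the peak
  annotation) — qualification is locus-to-promoter overlap, which is the
  quantity the summary describes.
- Empirical p-values always use the add-one estimator; identical seeds
  reproduce permutation results bit-for-bit, and the global RNG stream is
  saved and restored around every seeded routine.
- Problem sizes in the shipped suites are desk-scale by design: 1,000
  genes for recovery and calibration statements (±3 points on planted
  fractions), 500 replicates × 999 permutations for calibration bands,
  200 random ≤10 kb genomes for oracle equivalence, 100 seed pairs for
  the coupling contrast.

# Known limitations

- The shuffle null treats chromosomes as homogeneous; GC, mappability or
  blacklist structure would need the (absent by default) masking layer.
- Decile matching absorbs moderate covariate confounds; an extreme
  within-bin gradient would require more bins, at the cost of feasibility
  of within-bin sampling.
- Cross-dataset locus matching assumes pre-mapped coordinates; no liftover
  is performed.
- The logistic stratum model is descriptive (no covariate adjustment
  beyond the strata themselves).
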