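# trconverge

Convergent binding analysis for panels of transcriptional regulators (TRs)
profiled by ChIP-seq, integrated with open-chromatin (ATAC-seq) and
histone-mark tracks. The package asks whether a set of regulators — for
example, five autism-associated TRs (ARID1B, BCL11A, FOXP1, TBR1, TCF7L2)
profiled in developing cortex — converge on the same regulatory loci, and
whether that convergence is predictive of gene expression and enriched in a
gene set of interest.

## What it computes

- **Promoter-centric annotation.** Promoters are the 2,000 bp immediately
  upstream (5′, strand-aware, TSS base excluded) of every transcript TSS,
  unioned per gene. A peak overlapping any promoter window by ≥ 1 bp is
  *proximal* (crediting every overlapped gene); any other peak is *distal*
  and assigned its nearest TSS.
- **Independent loci and combinatorial membership (the "5TRa" framework).**
  Overlapping TR peaks are merged transitively into maximal independent
  loci; each locus records which assays overlap it. A *5TRa* locus is bound
  by all five TRs and overlapped by an ATAC peak. UpSet-style counts,
  peak-/nucleotide-level overlap fractions, per-locus maximum conservation
  scores, and distal locus-to-gene window linking (100 kb / 500 kb) follow.
- **Rank concordance.** Per assay, the top-N peaks by peak-caller p-value
  (ties broken by genomic location) are intersected pairwise; Spearman's ρ
  is computed over the within-top-N ranks of intersecting peaks, and panels
  are compared by a two-sided Wilcoxon rank-sum test.
- **Enrichment statistics.** A length-preserving interval-shuffle
  permutation null for overlap counts, with empirical
  p = (1 + #{null ≥ obs}) / (1 + n_perm); a covariate-matched gene-set
  permutation (null sets drawn within cDNA-length decile bins, absorbing
  the length confound); Pearson χ² (df = 1, no continuity correction) and
  two-sided Fisher tests on 2×2 tables with odds ratio ad/bc; BH/Bonferroni
  correction; DEX filtering (|FC| ≥ 2, p.adj ≤ 0.05, inclusive); expression
  stratification by bound-TR count with a logistic model of robust
  expression (log₂(TPM+1) ≥ 1); per-tissue enhancer-activity odds ratios;
  and ΔΔCt relative quantification (2^(−ΔΔCt)).
- **Synthetic data with ground truth.** A generator plants co-bound "hub"
  promoters, coupled p-value ranks, expression rising with TR count, a
  conservation track, a confounded gene set, and a DGE table — so every
  stage is testable without downloads.

All user-facing functions take tibbles and return tibbles; results carry
broom-style `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
figures.

## Worked example

```r
library(trconverge)

res <- run_pipeline(run_config(
  synthetic = synthetic_config(seed = 42, n_genes = 500),
  out_dir = tempfile(), n_perm = 999, seed = 43))
res$summary
#>    quantity                          value
#>  1 n_loci                         1106
#>  2 n_proximal_loci                 460
#>  3 pct_proximal_5tr                 32.2
#>  4 pct_5tr_with_atac               100
#>  5 pct_singletr_with_atac           12.8
#>  6 pct_geneset_proximal_signature   84.3
#>  7 pct_geneset_linked_100kb         60.8
#>  8 pct_geneset_linked_500kb         96.1
#>  9 conservation_fraction_above      99.3
#> 10 mean_rho                          0.486
#> 11 shuffle_p                         0.001
#> 12 geneset_perm_p                    0.001
#> 13 chi2                            184.
```

Reading the output: of 460 proximal loci, 32.2% are bound by all five TRs,
and essentially all of those carry concurrent open chromatin (100%) while
single-TR loci rarely do (12.8%) — the convergence signature. 84.3% of the
bundled gene set has a proximal 5TRa locus; the five-TR panel shows a mean
pairwise rank ρ of 0.49; the shuffle and length-matched permutation tests
both reject at their floor (p = 0.001 with 999 permutations):

```r
tidy(res$enrichment$shuffle)
#>   statistic            observed null_mean null_sd n_perm p_empirical
#> 1 n_query_overlapping       149      17.7    3.94    999       0.001
```

Expression rises with the number of proximally bound regulators; fully
co-bound promoters are almost all robustly expressed:

```r
res$enrichment$strata$by_tr_count
#>   proximal_tr_count     n median frac_robust
#> 1                 0   115  0.328       0.148
#> 2                 1   148  0.638       0.331
#> ...
#> 6                 5   150  3.32        1
```

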