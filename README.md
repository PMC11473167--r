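# trasplice

Analysis of promiscuous self-antigen expression and pre-mRNA splicing in
thymic epithelial RNA-seq.

Medullary thymic epithelial cells (mTECs) express thousands of
tissue-restricted antigen (TRA) genes to tolerize developing T cells.
Two regulators shape that repertoire: the transcriptional facilitator
**Aire**, and **Prmt5**, an arginine methyltransferase whose loss cripples
spliceosome function so that TRA transcripts accumulate unspliced introns
and lose mature expression. `trasplice` implements the complete desk-scale
computational analysis of this system for bulk RNA-seq across
control / Prmt5-KO / Aire-KO genotypes, driven by a ground-truth synthetic
data generator so that every stage is testable offline.

## What it computes

* **TRA classification** — Shannon entropy of each gene's atlas profile,
  $H = -\sum_t p_t \log_2 p_t$; a gene is a TRA when $H < 3.0$ bits
  (`entropy_score()`, `classify_tras()`).
* **Feature counting** — exon/intron assignment of read intervals against
  gene models (any intron overlap ⇒ intronic; ambiguous multi-gene reads
  discarded) and RPKM (`count_reads()`, `rpkm()`).
* **Differential expression & categories** — per-gene Student's t tests on
  $\log_2(\mathrm{RPKM}+0.01)$ in both knockout contrasts; expressed TRAs
  partition into `TRA_Prmt5` / `TRA_Aire` / `TRA_shared` / `TRA_other` by
  their down-regulation flags ($p<0.05$ and fold change $<0.5$)
  (`diff_test()`, `categorize_tras()`, `summarize_categories()`).
* **Intron retention** — per-gene index $r = i/(e+i)$ from pooled group
  counts, knockout/control fold change with flags $>1.5$ / $<0.75$ after a
  ≥10-read filter (`intron_retention_index()`, `retention_fold_change()`).
* **Diversity & statistics** — Shannon–Weaver $H' = -\sum p_i \ln p_i$ of
  the TRA repertoire per sample, ANOVA + Dunnett comparisons, Pearson
  correlation of retention vs expression change, Benjamini–Hochberg FDR
  over category retention tests (`shannon_weaver()`,
  `diversity_compare()`, `pearson_cor()`, `bh_fdr()`).
* **Simulation** — negative-binomial totals with a binomial intron split,
  planted dependence classes, effect sizes and splicing deficits, plus BED
  read intervals that re-count bit-exactly (`simulate_dataset()`,
  `simulate_read_intervals()`).

## Worked example

Summarizing a categorized TRA repertoire from its four class counts:

```r
library(trasplice)
summarize_categories(c(168, 576, 651, 1471))
#> $total
#> [1] 2866
#> $counts
#>  TRA_Prmt5   TRA_Aire TRA_shared  TRA_other
#>        168        576        651       1471
#> $percent
#>  TRA_Prmt5   TRA_Aire TRA_shared  TRA_other
#>        5.9       20.1       22.7       51.3
#> $prmt5_dependent_aire_share
#> [1] 79.5
```

5.9% of the expressed TRA repertoire depends on Prmt5 alone, 22.7% on both
regulators, and 79.5% of all Prmt5-dependent TRAs (651 of 168 + 651) are
also Aire-dependent.

Running the whole pipeline on a simulated dataset:

```r
rep <- run_pipeline(pipeline_config(
  simulation_params(n_genes = 500, mean_depth = 5e5, seed = 42)))
rep
#> run_report (simulate mode, seed 42)
#>   genes 500, samples 9, TRAs 125, expressed 488
#>   expressed TRA categories: TRA_Prmt5=4, TRA_Aire=24, TRA_shared=30,
#>     TRA_other=67 (total 125)
#>   retention~expression Pearson r = -0.935 (p = 3.39e-57)
```

The 125 planted TRAs are recovered and split into their dependence
classes, and the strong negative correlation shows the planted coupling:
genes that lose expression in the Prmt5 knockout are the ones whose
intron retention rises. `make_report_figures(rep, "figs")` renders the
scatter, retention-panel and diversity plots;
`run_pipeline(cfg, out_dir = "out")` persists every intermediate table
(TSV) and the report (JSON). A thin command-line wrapper lives at
`inst/scripts/selfantigen-splice.R`.

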