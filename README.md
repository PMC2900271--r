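# dgetag

Tag-based digital gene expression (DGE) analysis in R: a complete, tested
pipeline from in-silico restriction digestion to differential expression,
enrichment, and qPCR validation.

## The problem

DGE (the high-throughput successor of SAGE) counts transcripts by sequencing
one 17 nt tag per mRNA, anchored at the transcript's 3'-most NlaIII site
(`CATG`). It is cheap, quantitative and genome-annotation-light, but its
analysis has specific structure that generic RNA-seq tooling does not cover:

* which genes are *measurable at all* (they need an NlaIII site with a full
  17 nt 3' flank) and which are *quantifiable* (their canonical tag must be
  unique to them);
* exact 17-mer matching of reads against a tag catalogue digested from both
  the transcriptome and the genome, with every read classified as
  unambiguous cDNA, ambiguous cDNA, genomic-only, or unmatched;
* tags-per-million (TPM) abundance profiles of a strongly long-tailed
  transcriptome;
* two-group differential expression of small-replicate count data.

`dgetag` implements this pipeline for experiments such as paired pre/post
training muscle-biopsy designs, and ships a synthetic-data generator that
reproduces the statistical structure of such a study (7 subjects × 2
timepoints with one failed library, long-tailed abundances, planted fold
changes, sequencing error, intergenic reads), so the whole pipeline is
testable end-to-end without any external download.

## The statistics at the core

Counts of tag *g* in sample *s* are modelled as negative binomial with mean
μ<sub>gs</sub> and a **common dispersion** φ: Var = μ + φμ². φ is estimated
by profile likelihood over a log-spaced grid, with group means fitted as
(group total / group library total) × library size. For testing, libraries
are scaled to their geometric mean size; conditional on a tag's total
T = S<sub>A</sub> + S<sub>B</sub>, the group sums are NB with sizes
n<sub>A</sub>/φ and n<sub>B</sub>/φ and the mean parameter cancels, giving an
exact discrete distribution over all T + 1 splits. The two-sided p-value is
the probability-ordering tail: Σ P(split) over splits no more probable than
the observed one. As φ → 0 this is exactly the binomial test. Significance
is controlled by Benjamini–Hochberg FDR; fold changes are
log2((TPM̄<sub>post</sub> + 0.5)/(TPM̄<sub>pre</sub> + 0.5)).

Downstream, gene-set overrepresentation uses the hypergeometric upper tail
with the conservative EASE penalty (one hit removed before the tail), and
ranked-list segmentation enrichment cuts the DE-ranked gene list at evenly
spaced ranks, Fisher-testing every term × cut 2×2 table with BH across the
whole family. qPCR validation fits a standard curve (Ct vs log2 dilution) to
a reference-gene dilution series, interpolates relative quantities,
normalises within-sample by the reference, and applies a paired t-test.

## Worked example

Simulate a small paired study, build the catalogue, count tags, and test for
differential expression:

```r
library(dgetag)
library(dplyr)

cfg <- sim_config(seed = 42, n_genes = 100, genome_length = 150000,
                  transcript_length = c(150, 300), library_size = 20000,
                  n_subjects = 7, de_fraction = 0.08)
sim     <- generate_genome_models(cfg)
catalog <- build_catalog(sim$gene_models, sim$genome)
catalog_stats(catalog, sim$gene_models)
#> # A tibble: 1 × 6
#>   n_genes n_genes_with_site n_genes_unique_canonical frac_with_site ...
#> 1     100                91                       79           0.91
```

91% of the simulated genes carry a usable NlaIII site and 79% have a
gene-unique canonical tag — the two quantifiability fractions the catalogue
module computes for any transcriptome.

```r
truth   <- simulate_truth(cfg, sim$gene_models$gene_id)
lib     <- simulate_libraries(truth, catalog, cfg)
tags    <- lib$reads |> count(sample_id, seq, name = "count") |> rename(tag = seq)
matched <- match_and_count(tags, catalog)
genes   <- gene_counts_tpm(matched, catalog)
head(abundance_profile(genes), 3)
#>   gene_id total_reads pct_all cumulative_pct
#> 1 G0100         29601   19.5            19.5
#> 2 G0043         21980   14.5            34.0
#> 3 G0044         14977    9.86           43.8

de <- run_de(matched$counts, lib$sheet)
de
#> Tag-level differential expression (NB exact test)
#>   tags tested: 73 (filtered: 2)
#>   common dispersion: 0.1778
#>   significant at FDR 0.05: 10
head(tidy(de), 3)
#>   tag               mean_tpm_pre mean_tpm_post log2_fc        p    adj_p significant
#> 1 TTGCAACGATGT...         14700.       166192.    3.50 1.33e-19 9.69e-18 TRUE
#> 2 AGGAGTACATTC...          1722.          215.   -3.00 5.54e-10 2.02e- 8 TRUE
#> 3 TGCGCTGATGAT...          2486.          464.   -2.42 1.08e- 8 2.63e- 7 TRUE
```

The top abundance rows show the long-tailed transcriptome shape (three genes
already hold 44% of annotated reads); the DE table reports, per tag, group
mean TPMs, the log2 fold change, the exact-test p and its BH adjustment.
`glance(de)` gives the one-row run summary, `autoplot(de)` a volcano plot,
and `fatiscan(de_ranking(...), annotation)` the ranked enrichment scan.
`run_pipeline(pipeline_config(...))` drives all stages from files on disk
and writes fixed-layout TSV/JSON outputs plus a manifest.

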