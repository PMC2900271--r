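---
title: "Tag-based digital gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-based digital gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgetag)
library(dplyr)
```

## The measurement model

Tag-based digital gene expression (DGE) counts transcripts by sequencing a
single short tag per mRNA molecule. The library chemistry captures mRNA on
oligo(dT) beads, cuts with NlaIII (recognition site `CATG`), and releases a
17 nt fragment immediately 3' of the cut — so each transcript is represented
by the tag at its **3'-most** NlaIII site (the *canonical* tag; internal
sites yield *noncanonical* tags at higher ranks). Tag counts are therefore a
direct, hypothesis-free census of the transcriptome, with two structural
blind spots that the catalogue module quantifies:

* a transcript without any `CATG` followed by a full 17 nt flank produces no
  tag at all — such genes are invisible to the assay;
* an identical 21-mer (`CATG` + tag) shared by two or more genes makes the
  tag ambiguous — such genes cannot be quantified unambiguously.

`extract_tags()` implements the digestion rule exactly: a site qualifies iff
it has ≥ 17 nt of 3' flank and the emitted 17-mer contains no `N`; ranks
count qualifying sites from the 3' end, so rank 1 falls back upstream past
disqualified sites. `catalog_stats()` calls a gene *quantifiable* when at
least one of its canonical tags is carried by no other gene. We deliberately
use canonical tags only for quantifiability — the chemistry's expected
product — while `gene_counts_tpm()` sums all unambiguous tags (any rank) of
a gene, since noncanonical tags from partial digestion still identify the
gene uniquely.

Coordinates are 0-based half-open everywhere except written GFF3 (1-based
closed, per that standard). Genomic digestion scans both strands; `CATG` is
its own reverse complement, so plus- and minus-strand sites share a forward
anchor, recorded at the first base of `CATG`.

## Read handling and counting

The published description of upstream quality filtering in this assay class
is typically opaque ("pipeline quality filters"), so `filter_reads()` uses an
explicit, configurable rule: keep reads of exactly 17 nt, with no `N`, and
all base qualities ≥ Q20. Matching against the catalogue is **exact**: with
17-mers, one substitution almost always maps a real tag out of the catalogue
(or onto a different entry), and allowing mismatches would conflate
sequencing error with SNPs. Each distinct tag classifies into exactly one of
four categories — unambiguous cDNA, ambiguous cDNA, genomic-only, unmatched —
and these partition the usable reads. A tag unique to one gene remains
unambiguous even if its sequence also occurs in intergenic genome: the gene
assignment takes precedence, and genome overlap is reported separately in
the accounting.

The TPM denominator is the per-sample total of *unambiguous cDNA* reads (the
annotated transcriptome), not all usable reads; abundance-profile
percentages are shares of that same denominator, so the cumulative column
ends at 100%.

## The differential-expression model

Counts for a tag across biological replicates are modelled as negative
binomial with a **common dispersion** φ shared by all tags:
Var(Y) = μ + φμ². Two estimation/testing choices matter:

* **Dispersion** is estimated by maximising the profile log-likelihood over
  a fixed grid (default 61 log-spaced points in [10⁻⁶, 10]), with per-tag
  per-group fitted means `(group total / group library total) × sample
  library size`. A grid argmax is deterministic, trivially reproducible, and
  easy to validate against simulation (a test cross-checks it against
  edgeR's quantile-conditional estimator to within a quarter of a decade).
* **Testing** conditions on each tag's total count T across both groups
  after scaling all libraries to their geometric mean size (rounded to
  integers; a documented simplification of quantile equalisation). Group
  sums of n equalised NB samples are NB with size n/φ, and conditionally on
  T the mean parameter cancels, leaving a discrete distribution over the
  T + 1 splits. The two-sided p-value sums the probabilities of all splits
  no more probable than the observed one (probability ordering — the
  standard construction for asymmetric exact conditional tests; tail
  doubling can exceed 1 and behaves badly at the mode). As φ → 0 this
  collapses to the exact binomial test, which the test suite verifies to
  |Δp| < 10⁻⁶ for all totals up to 200.

Fold changes are reported unambiguously as `log2_fc = log2((mean TPM_post +
0.5) / (mean TPM_pre + 0.5))`; the 0.5 TPM pseudocount keeps zero-count
groups finite without materially shrinking moderate ratios. Multiplicity is
controlled by Benjamini–Hochberg step-up FDR (via `stats::p.adjust`).

Subject pairing is recorded in the sample sheet but **not modelled**: the
exact conditional test is an unpaired two-group comparison (the classic mode
of the count-based DE tools this pipeline follows). Tags with total count
below 5 across all samples are excluded before testing (configurable, and
reported in the result object) — such tags cannot reach significance and
only dilute the FDR correction.

## Enrichment

Two complementary views:

* `ease_scan()` tests a gene *set* (e.g. all expressed genes) against a
  background universe per term, using the hypergeometric upper tail with the
  **EASE penalty**: one observed hit is removed (floored at zero) before the
  tail computation. This is deliberately conservative — a term supported by
  a single gene can never be significant — and the suite verifies
  `p_EASE ≥ p_Fisher` on random tables. Fold enrichment is always computed
  from unpenalised counts. The default background is the full gene-model
  set.
* `fatiscan()` detects terms asymmetrically distributed along a *ranked*
  list without any significance cutoff: the list is cut at 30 (default)
  evenly spaced ranks, each term × cut 2×2 table gets a two-sided Fisher
  test, and BH runs across the full term × partition family — conservative,
  but it avoids choosing a single arbitrary cut. Each term reports its best
  cut, direction, and minimum adjusted p. The cut set is symmetrised
  (k and N−k), which makes reversal of the ranking an exact symmetry:
  directions flip, p-values are preserved. The ranking score feeding it from
  a DE result is `sign(log2_fc) × (−log10 p)`, the conventional signed
  significance score.

GO hierarchy is not traversed; terms are flat labels from the annotation
file. Term-level reporting filters (e.g. "GO level > 6") are presentation
filters on a metadata column, not part of the statistics.

## qPCR validation

The standard-curve method regresses Ct on log2(dilution factor) for a serial
dilution of a reference sample: slope is cycles per two-fold dilution (1.0
at perfect efficiency), and per-cycle efficiency is `2^(1/|slope|) − 1`.
Quantities interpolate as `2^((intercept − Ct)/slope)`, duplicates are
averaged on the Ct scale first, and each target is normalised by the
reference gene's quantity in the same sample — making results invariant to
per-sample input amounts. Fold change is the ratio of post to pre means of
the normalised quantities, with a paired two-sided Student's t-test on
per-subject differences (df = pairs − 1). The test runs on **linear**
quantities by default, matching the ratio-of-means fold change being
reported; a log2 option exists for users who prefer symmetric errors.
Zero-variance differences are flagged rather than tested.

## What the synthetic data emulates — and what it does not

The generator reproduces the statistical structure the pipeline assumes:

* **Design**: 7 subjects × pre/post timepoints with one pre library dropped
  (13 libraries), subject identifiers retained.
* **Catalogue structure**: ~9% of genes built with no qualifying site, ~13%
  in pairs sharing their 3'-terminal 21-mer; all other genes end in `CATG` +
  a unique random 17-mer, so canonical tags sit at the 3' terminus and
  internal sites arise by chance.
* **Abundance**: log-normal baselines with sdlog σ = 2.6, normalised to a
  composition. σ was calibrated once by Monte Carlo so that the top 28 of
  5,000 genes jointly hold ≥ 40% of the reads in ≥ 80% of draws (mean share
  ≈ 51%) — the "a couple of dozen genes are half the transcriptome" shape
  that deep tag profiling of skeletal muscle shows. Smaller σ (e.g. 2.2)
  fails that property in most draws.
* **Counts**: per-gene gamma weights (shape 1/φ, default φ = 0.2, a typical
  between-animal overdispersion) scaled by the multinomial draw over the
  exact genic library size — a gamma-mixed Poisson conditioned on its total,
  so per-sample read totals are conserved exactly while marginals keep NB
  overdispersion. Planted log2 fold changes (default |lfc| ∈ [0.5, 4.9],
  matching the magnitudes a training study reports) multiply post-timepoint
  means before renormalisation. Because TPMs are compositional, planting a
  large change on a dominant gene attenuates everyone's observed ratios;
  power analyses therefore plant effects on moderately abundant genes.
* **Reads**: every genic read emits its gene's canonical tag (noncanonical
  leakage available behind a flag), a configurable intergenic fraction
  (default 0.3, mirroring the large genomic-only read fraction such studies
  observe) draws from genomic-only tags, and uniform per-base substitution
  errors (default 0.005) create unmatched tags. Default depth is 200,000
  reads per library — a deliberate scale-down from the millions of usable
  reads per library in a real study, chosen so a full simulated experiment
  runs in seconds while keeping per-tag counts large enough for the exact
  test to be informative.
* **qPCR**: Ct = 35 − log2(relative abundance × timepoint effect) + Gaussian
  noise, duplicate wells, a synthetic reference gene (constant abundance,
  zero fold change) and its 1:1…1:64 dilution series.

Each sample draws from an independently derived random stream, so dropping a
library leaves all other libraries byte-identical, and every generator
output is a pure function of (config, seed).

What it does **not** emulate: quality-score-correlated errors, adapters or
chimeras, isoform switching, 3'-UTR annotation error, or the real genome's
repeat structure. Passing tests therefore demonstrate correctness of the
*algorithms* under the stated model, not robustness to every artefact of
real libraries.

## Numerical choices and edge cases

* Exact-test tie handling uses a relative tolerance of 10⁻⁷ when comparing
  split probabilities, so floating-point-equal symmetric splits are counted
  into the tail (the same convention `binom.test` uses).
* The conditional split distribution is computed in log space and
  renormalised; the suite asserts normalisation to 1 ± 10⁻¹⁰.
* `T = 0` gives p = 1; empty sequences digest to empty tag lists; an
  all-zero count matrix, an empty gene-model set, an empty foreground, and
  a flat standard curve are rejected with informative errors.
* Ranked-list ties are broken deterministically by gene id; catalogue
  statistics are invariant to gene and transcript order.
* Library equalisation rounds to integers; with library sizes within a
  few-fold of each other the rounding perturbs group sums by well under a
  count per sample on average.

## Problem sizes used in the shipped checks

The packaged verification suite runs the full pipeline on simulated studies
of 60–500 genes at 2,000–200,000 reads per library, 20 simulation
replicates for FDR control and power, 100 permutation replicates for the
ranked-scan null, and 1,000 random sequences for the digestion oracle —
sizes chosen so the whole suite completes in a couple of minutes on one
core while keeping Monte-Carlo error well inside the asserted margins. The
same code paths scale linearly in reads and tags for real-sized inputs.

## Known limitations

* Common dispersion only: no tagwise/trended dispersion, no GLM designs, no
  TMM normalisation, and no modelling of the paired structure.
* Exact matching only: SNPs and sequencing errors in a tag lose the read
  (reported, not recovered); no de novo assembly of unmatched tags.
* Proximity annotation is strand-agnostic and reports ties; it is a
  reporting aid for DE tags, never used to inflate gene counts.
* The EASE/Fisher machinery treats annotation as flat sets; no GO DAG
  propagation.
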