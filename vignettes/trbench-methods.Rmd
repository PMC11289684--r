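---
title: "Benchmarking transcriptional regulator ranking: models and design"
author: "trbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking transcriptional regulator ranking: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trbench)
```

## The problem

Given a query gene set — typically the most significant differentially
expressed (DE) genes from a transcriptional regulator (TR) knockdown or
knockout experiment — which TR regulates it? A family of computational
methods answers this by comparing the query against compendia of TR
ChIP-seq "fingerprints": each dataset records the binding sites (peaks) of
one TR, and the methods rank all TRs (or all TR datasets) by how strongly
their binding profile associates with the query. Two method families
dominate practice:

* **Library-based** methods first convert each TR dataset's peaks into a
  target-gene (TG) set using the linear distance between peaks and
  transcription start sites (TSSs), then test each TG set for enrichment
  with the query against a background universe (Fisher's exact test,
  usually one-sided, with Benjamini-Hochberg correction).
* **Region-based** methods skip TG assignment and work with cis-regulatory
  regions directly: the proportion of a dataset's peaks falling in
  query-gene promoters (two-sided Fisher), the separation of per-gene
  maximum peak signals between query and background (two-sample
  Kolmogorov-Smirnov with a top-signal scaling factor), or a regulatory
  potential (RP) model over H3K27ac/DNase epigenome tracks with in-silico
  deletion (ISD) of a TR's binding loci, Wilcoxon tests and Cauchy p-value
  combination; a fourth variant scores a DHS-like candidate-site universe
  and ranks TRs by the AUC with which those scores predict each dataset's
  peak presence.

trbench re-implements the algorithmic core of both families together with
the complete evaluation framework used to compare them — hit rate, mean
reciprocal rank (MRR), mean average precision (MAP) and mean normalized
discounted cumulative gain (mNDCG) at a rank threshold $K$, percentile hit
counts, pairwise method combination, and a multi-dataset bias analysis —
and exercises everything end-to-end on synthetic regulatory-genomics data
with planted ground-truth regulators. Nothing is downloaded; every input
is generated by code.

## The evaluation framework

For ranking lists $i = 1, \dots, N$ with relevance indicators
$R_{ik} \in \{0, 1\}$ at ranks $k = 1, \dots, K$ (a term is relevant when
it names the perturbed TR; a per-dataset list can contain several relevant
terms, capped by that TR's dataset count) and $n_{iK} = \sum_k R_{ik}$:

$$H_K = \frac{1}{N}\sum_i \mathbf{1}\{n_{iK} > 0\}, \qquad
  \mathrm{MRR}_K = \frac{1}{N}\sum_i \frac{1}{k_i^\ast}$$

with $k_i^\ast$ the first relevant rank,

$$\mathrm{MAP}_K = \frac{1}{N}\sum_i \frac{1}{n_{iK}}
  \sum_{k: R_{ik}=1} \frac{\#\{j \le k: R_{ij}=1\}}{k}, \qquad
  \mathrm{mNDCG}_K = \frac{1}{N}\sum_i
  \frac{\sum_k R_{ik} / \log_2(k+1)}{\sum_{k=1}^{n_{iK}} 1/\log_2(k+1)}.$$

Two corners are undefined by the formulas and resolved here as explicit
conventions: a list with no relevant term above $K$ contributes 0 to
$\mathrm{MRR}_K$ (the argmin does not exist), and lists with $n_{iK} = 0$
contribute 0 to $\mathrm{MAP}_K$ and $\mathrm{mNDCG}_K$ (their $1/n_{iK}$
is undefined). These conventions keep $\mathrm{MRR}_K \le H_K$ for every
input. Percentile hits use a ceiling threshold,
$\mathrm{rank} \le \lceil q L \rceil$ for list length $L$. All four
metrics are verified against independent naive-loop implementations at
$10^{-12}$ tolerance.

For the bias analysis, each list yields a one-sided Wilcoxon rank-sum
p-value $p_i$ comparing the best ranks of deeply profiled TRs with those
of single-dataset TRs; lists whose perturbation target is among the
selected TRs are excluded so that the remaining queries act as random sets
with respect to the selection. The $p_i$ are integrated by Stouffer's
method, $Z_i = \Phi^{-1}(1-p_i)$, $Z_c = \sum_i Z_i / \sqrt{I}$,
$p_c = 1 - \Phi(Z_c)$.

## The synthetic universe

The generator defaults *are* the study conditions for every test and for
`scripts/acceptance.R`; they were fixed once, by pilot simulation, to
place the benchmark in the regime the evaluation assumes — a planted
signal strong enough that a sensible ranker finds it, yet imperfect enough
that design choices (window cutoffs, input size) visibly matter, as they
do on real data. The moving parts, with defaults:

* **Gene universe**: 5,000 genes on 5 chromosomes of 20 Mb, TSSs on a
  jittered grid (~20 kb spacing, no collisions), random strands.
* **TR panel**: 50 TRs; 40% are "deeply profiled" with 10 ChIP-seq-like
  datasets each, the rest have one (230 datasets total), mirroring the
  skewed allocation of profiling effort across factors.
* **Overlapping target programs**: each TR draws 150-250 target genes
  weighted by a log-normal gene "popularity" (sdlog 2). Popular hub genes
  are therefore shared across many TR programs, as in real regulatory
  networks; disjoint target sets would make the ranking task unrealistically
  easy.
* **Binding-distance spectrum**: every TR has its own peak-displacement
  scale, log-spaced over 0.3-5 kb across the panel and assigned with the
  distal (enhancer-biased) end going to the deeply profiled TRs. A
  true-target peak falls near the target's TSS (Normal displacement with
  the TR's scale) with probability 0.9 and otherwise uniformly within
  ±100 kb. This heterogeneity is what makes a TSS-window cutoff re-order
  TRs.
* **Peaks and signals**: 200-bp peaks; log-normal signals (meanlog 0,
  sdlog 0.5) with a ×3 boost for true-target peaks; 60 nonspecific peaks
  per dataset at popularity-sampled hub genes (high-occupancy-target
  regions that attract ChIP signal for almost every factor) and 300
  uniform background peaks.
* **Epigenome tracks**: 10 tracks alternating H3K27ac/DNase; 6 are
  informative, each emulating a cell type in which a random half of the TR
  programs is active (boosted peaks near the covered targets' TSSs, SD
  1 kb), the others pure background.
* **Query cases**: each case picks a TR uniformly, takes a shuffled subset
  of its targets ("most significant" first) and pads with noise genes so
  that the noise fraction is 0.65 at $G = 200$, 0.80 at $G = 600$ and 0.90
  at $G = 1000$ (linearly interpolated elsewhere, constrained
  non-decreasing). Noise genes are drawn by popularity, emulating indirect
  knockdown effects that cascade through highly regulated hub genes — this
  is deliberately the hard part: direct-binding/DE concordance is low in
  real perturbation data, and uniform noise would leave the planted TR
  trivially recoverable.

What the generator does **not** emulate: 3D chromatin contacts, chromatin
domains, cell-type-specific expression baselines, peak-calling artifacts
beyond the HOT mechanism, gene-length and GC biases, and real DE
statistics (significance order inside a case is true-targets-first by
construction). Passing tests therefore demonstrate algorithmic
correctness and the qualitative phenomena above, not performance on any
real compendium.

All coordinates are BED-style 0-based half-open. Distances are measured
from the peak midpoint `floor((start + end) / 2)`; the choice of midpoint
(rather than summit or nearest edge) is symmetric and deterministic.
Nearest-gene ties go to the lexicographically smallest symbol. Every
generator output is a pure function of `(config, seed)`, and the pipeline
derives per-stage seeds from one root seed via named substreams.

## Ranker-specific choices

* **Library rankers**: background defaults to all annotated genes; the
  query is carved out of the background inside the 2×2 table (rows: query
  vs background∖query), giving a well-defined partition. Default
  sidedness is one-sided ("greater"); two-sided is exposed because some
  deployed tools use it. BH correction is applied across the datasets of
  one run — one multiple-testing family per ranking list. The optional
  Enrichr-style correction simulates random queries of the same size and
  standardizes each dataset's observed Fisher rank, $z = (\mathrm{rank} -
  \overline{\mathrm{rank}})/\mathrm{sd}$ (sd floored at $10^{-9}$); $z$
  and $p$ are reported separately rather than blended into a combined
  score.
* **Fisher's exact test** is computed from the hypergeometric support;
  the two-sided p sums point probabilities $\le$ the observed one with
  the standard $1 + 10^{-7}$ relative slack against floating-point ties.
  Tests verify agreement with full-support enumeration (margins to 60) at
  $10^{-10}$.
* **Promoter-proportion ranker**: strand-aware promoter windows, 5 kb
  upstream and 0.5 kb downstream of the TSS by default. The reference
  column of its 2×2 is the pooled peaks of all datasets; a gene-count
  reference is available. A peak overlapping both a query-gene and a
  background-gene promoter counts as query.
* **Max-signal K-S ranker**: per-gene maximum signal within ±5 kb of the
  TSS; exact K-S p for tie-free groups of ≤ 25, asymptotic otherwise;
  score = $-\log_{10}(q)$ × a scaling factor, the ratio of top-5% mean
  signals (query vs background) with ceiling counts ≥ 1, clamped to
  $[10^{-3}, 10^3]$ to survive sparse profiles.
* **RP model**: $\mathrm{RP}(g) = \sum_{d \le w} s \cdot 2^{-d/h}$ over
  peak midpoints within $w = 10$ kb of the TSS, half-life $h = 1$ kb
  (uniform weights available). A peak exactly one half-life away
  contributes half its signal.
* **Stepwise selection**: forward selection on standardized
  $\log(1+\mathrm{RP})$ by AIC; zero-variance samples are never
  candidates; the first step always takes the best candidate (the model
  must use at least one sample), later steps require an AIC improvement;
  the cap is `max_k`. Complete separation falls back to a ridge-penalized
  fit with a warning.
* **ISD / Lisa-style ranker**: deletion zeroes track peaks overlapping the
  dataset's peaks extended by ±1 kb; ΔRP is propagated through the fitted
  model's linear predictor (coefficient-weighted change), and query vs
  background is compared by one-sided Wilcoxon ("greater": a functional
  TR should raise ΔRP and peak-RP for query genes) for ΔRP-H3K27ac,
  ΔRP-DNase and peak-RP, combined by the Cauchy test. On this generator
  every dataset's component p-values saturate far below machine-visible
  scales, so the combination runs on the log scale (asymptotic
  $\tan((1/2 - p)\pi) \approx 1/(\pi p)$ for tiny p), which preserves the
  ordering that a fixed clipping bound would erase. The exported
  `cauchy_combine()` keeps the conservative $[10^{-15}, 1-10^{-15}]$ clip
  as its default.
* **DHS/AUC (BART-style) ranker**: the candidate-site universe is the
  reduced union of all track peak intervals; site scores are the selected
  tracks' $\log(1+\mathrm{signal})$ weighted by the model coefficients on
  their fitted scale; per-TR Wilcoxon of its datasets' AUCs against all
  AUCs; the top AUC is standardized against `n_null_sets` random queries
  (default 100, a deliberately scaled-down stand-in for a large
  pre-collected gene-set panel); the final rank averages the three
  component ranks, ties broken by TR name.
* **Wilcoxon rank-sum**: exact (via `wilcox.test`) for tie-free groups of
  ≤ 12; otherwise a tie-corrected normal approximation *without*
  continuity correction — the uncorrected tail behaves like a mid-p with
  $E[\Phi^{-1}(1-p)] = 0$ under the null, which keeps Stouffer-combined
  p-values uniform where the continuity-corrected version is visibly
  biased.
* **TR-level collapsing**: wherever a per-dataset ranking must be read at
  TR level (bias analysis, Jaccard overlap, combination), the TR's rank is
  the best (minimum) of its dataset ranks — how users read such lists; the
  mean-rank alternative is exposed in `integrate_tr_ranks()`.
* **Ties** everywhere break lexicographically (dataset id or TR name) so
  that every ranking is deterministic.

## Problem sizes used by the tests and the acceptance script

The shipped checks run the default universe (5,000 genes, 230 datasets)
with 100 query cases per input size for the library-based analyses
(recovery, sensitivity, cutoff instability), 15-20 cases for the
K-S/combination analyses, 10 cases for the ISD ranker, 50-100 seeded runs
for the selection-rate property, and 50 lists × 200 replicates for the
bias calibration. These sizes were chosen so the planted-signal
proportions are estimated with standard errors of a few percent while the
whole suite stays comfortably reproducible on a laptop; all of them are
orders of magnitude below the real study's scale (570 perturbation gene
sets against tens of thousands of datasets), which is exactly why the
acceptance checks are property-based rather than attempts to reproduce
the published headline numbers.

## Known limitations

* The density (ChEA3-style) assignment retains the top 5% of non-zero
  aggregate scores; with 150-250 planted targets per TR this keeps ~30-40
  genes, so its *recall* of the planted set is structurally low — the
  shipped checks assert high *precision* instead. The aggregation kernel
  (linear taper, exponential option) is a declared stand-in; the deployed
  tool does not document its kernel.
* The promoter-proportion reference margin, the K-S score rescaling, the
  RP decay and window, the ISD flank, Wilcoxon sidedness and the Cauchy
  weights are all documented package choices where deployed tools leave
  the detail unspecified; each is a tunable argument.
* Enrichr's blended "combined score" is not reproduced; $z$ and $p$ are
  reported separately.
* The BART-style ranker's null calibration uses simulated random queries,
  not a curated gene-set panel, and inherits that panel's absence.
* With one ground-truth TR per case (single-TR perturbations), relevance
  matching is by TR name; co-regulation is present in the generator (hub
  genes) but never labelled as relevant.
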