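# trbench

Benchmarking computational methods that rank **transcriptional regulators
(TRs)** from a query gene set.

Given the differentially expressed genes of a TR knockdown experiment,
NGS-based tools rank candidate regulators by comparing the query against
compendia of TR ChIP-seq "fingerprints". trbench re-implements the
algorithmic core of the two method families used in practice and the full
ranking-evaluation framework, and exercises everything end-to-end on
synthetic regulatory-genomics data with *planted* ground-truth regulators —
so every stage is testable without downloading any compendium.

For researchers developing or evaluating TR-prioritization methods, the
package provides:

* **Synthetic universe generator** — gene annotation with strand-aware
  TSSs; TR ChIP-seq-like peak datasets with per-TR binding-distance
  profiles, hub-gene (HOT) peaks and skewed per-TR dataset multiplicity;
  H3K27ac/DNase-like signal tracks emulating cell-type-specific activity;
  ordered query gene sets mixing true targets with popularity-weighted
  noise.
* **Library-based rankers** — window / nearest-gene / peak-density
  target-gene assignment, one- or two-sided Fisher exact enrichment
  (`fisher_exact()`, verified against full hypergeometric enumeration),
  BH correction, simulation-based z-score rank correction, per-TR rank
  integration.
* **Region-based rankers** — promoter-proportion Fisher test
  (`chipatlas_rank()`), per-gene max-signal Kolmogorov-Smirnov ranking
  (`magic_rank()`), regulatory-potential model with in-silico deletion,
  stepwise logistic track selection, Wilcoxon + Cauchy combination
  (`lisa_rank()`), and DHS-scoring AUC ranking (`bart_rank()`).
* **Evaluation framework** — relevance matrices and the four ranking
  metrics at threshold K:

  hit rate `H_K = mean(n_iK > 0)`; `MRR_K = mean(1/k*_i)` over first
  relevant ranks; `MAP_K` averaging precision at relevant positions
  divided by `n_iK`; `mNDCG_K = mean(DCG_K / idealDCG)` with
  `1/log2(k+1)` discounts — plus top-percentile hit counts and missing-TR
  accounting.
* **Combination & bias analyses** — pairwise method combination by best
  rank, Jaccard overlap of top-K TRs, multi-dataset bias testing
  (one-sided Wilcoxon on best ranks, Stouffer's Z integration), and a
  cutoff-sensitivity harness.

## Worked example

```r
library(trbench)

# default study conditions: 5,000 genes, 50 TRs, 230 datasets,
# 100 query cases of 200 genes each
bench <- simulate_benchmark(generator_config(), seed = 1,
                            G = 200, n_cases = 100)
uni <- bench$universe

# window-based target-gene library (2 kb) + one-sided Fisher ranking
lib <- build_target_library(bench$datasets, uni$annotation,
                            "window", window = 2000)
rankings <- rank_library_cases(lib, bench$cases[["200"]],
                               uni$annotation$symbol)

truth <- vapply(bench$cases[["200"]], `[[`, "", "true_tr")
R <- build_relevance(rankings, truth, K = 10)
c(hit10 = hit_rate(R), mrr10 = mrr(R), map10 = map_at_k(R),
  mndcg10 = mndcg(R))
#>     hit10     mrr10     map10   mndcg10
#> 0.9100000 0.7965833 0.7765304 0.8212390
```

The planted regulator's best dataset lands in the top 10 (of 230 ranked
datasets) for 91% of the cases, with a mean reciprocal rank of 0.80 — the
planted TR is typically at rank 1-2. A random-permutation baseline
(`permute_ranking()`) reaches a Hit@10 of only ~0.20, most of it from the
deeply profiled TRs holding 10 of the 230 terms. Growing the query to
G = 1000 (noise fraction 0.90) collapses MRR@50 from 0.80 to below 0.01,
reproducing the qualitative sensitivity of these methods to noisy input,
and re-building the library across TSS windows of 1-10 kb moves the true
TR's rank by more than 5 positions in about a third of the cases — the
hard-cutoff instability that motivates cutoff-free designs.

A full configured run (simulate → build-library → rank → evaluate →
combine → bias, with a JSON manifest) is available as

```r
run_pipeline(list(rankers = c("window_fisher", "magic")), seed = 1,
             outdir = "run1")
```

or from the shell via `Rscript inst/scripts/trbench run --config cfg.yaml
--seed 1 --outdir run1`.

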