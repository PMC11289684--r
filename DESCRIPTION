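Package: trbench
Title: Benchmarking Transcriptional Regulator Ranking from Query Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained benchmark suite for computational methods that
    rank transcriptional regulators (TRs) given a query gene set, such as the
    differentially expressed genes from a TR knockdown experiment. Provides a
    synthetic regulatory-genomics generator with planted ground-truth
    regulators (gene annotation, TR ChIP-seq-like peak datasets with skewed
    per-TR multiplicity, H3K27ac/DNase-like signal tracks, ordered query gene
    sets), re-implementations of the two method families used in practice
    (library-based target-gene enrichment with window, nearest-gene and
    peak-density assignment; region-based promoter-proportion, max-signal
    Kolmogorov-Smirnov, regulatory-potential with in-silico deletion, and
    DHS-scoring AUC rankers), a ranking-evaluation framework (hit rate, mean
    reciprocal rank, mean average precision, mean NDCG, percentile hits), and
    pairwise method-combination and multi-dataset bias analyses with Stouffer
    and Cauchy p-value combination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    glmnet,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
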