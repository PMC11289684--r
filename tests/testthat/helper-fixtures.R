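# Shared fixtures and independent oracles. Everything is built in code at
# test time; the default-condition benchmark is simulated once per test run
# and cached for the files that need it.

tiny_annotation <- function() {
  gene_annotation(
    symbol = c("GATA1", "TAL1", "KLF1", "RUNX1", "SPI1", "MYB", "LMO2", "FLI1"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2", "chr2", "chr2"),
    tss = c(10000L, 30000L, 52000L, 81000L, 12000L, 41000L, 66000L, 90000L),
    strand = c("+", "-", "+", "+", "-", "+", "-", "+"))
}

tiny_peaks <- function(chrom, mids, width = 200L, signal = 1) {
  data.frame(chrom = chrom, start = as.integer(mids - width %/% 2),
             end = as.integer(mids - width %/% 2 + width),
             signal = signal, stringsAsFactors = FALSE)
}

random_annotation <- function(n, n_chroms = 2, span = 1e6) {
  gene_annotation(sprintf("g%04d", seq_len(n)),
                  sample(paste0("chr", seq_len(n_chroms)), n, replace = TRUE),
                  sample.int(span, n),
                  sample(c("+", "-"), n, replace = TRUE))
}

random_dataset <- function(annotation, n_peaks = 40, id = "d1", tr = "TRX",
                           span = 1e6) {
  chroms <- unique(annotation$chrom)
  mids <- sample.int(span - 1000L, n_peaks) + 500L
  peak_dataset(id, tr,
               tiny_peaks(sample(chroms, n_peaks, replace = TRUE), mids,
                          width = sample(100:400, n_peaks, replace = TRUE),
                          signal = round(runif(n_peaks, 0.1, 9), 3)))
}

# small universe for module-level tests (fast to simulate); ... overrides
# the small-scale defaults
small_config <- function(...) {
  args <- list(n_genes = 600L, n_chroms = 2L, chrom_length = 4e6,
               n_trs = 10L, targets_per_tr = c(40L, 60L),
               multi_fraction = 0.3, multi_datasets = 4L,
               background_peaks = 80L, hot_peaks = 15L,
               track_background_peaks = 400L,
               n_tracks = 6L, informative_tracks = 4L)
  over <- list(...)
  do.call(generator_config, c(over, args[setdiff(names(args), names(over))]))
}

small_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_benchmark(small_config(), seed = 11, G = 60,
                                   n_cases = 12)
    cache
  }
})

# default study conditions, simulated once (used by the acceptance tests)
default_bench <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_benchmark(generator_config(), seed = 1,
                                   G = c(200, 600, 1000), n_cases = 100)
    cache
  }
})

case_truth <- function(cases) vapply(cases, `[[`, "", "true_tr")

# ---- independent naive-loop oracles for the four ranking metrics ----

oracle_metrics <- function(R) {
  N <- nrow(R)
  K <- ncol(R)
  hit <- 0; rr <- 0; ap <- 0; ndcg <- 0
  for (i in seq_len(N)) {
    row <- R[i, ]
    n_i <- 0
    for (k in seq_len(K)) n_i <- n_i + row[k]
    if (n_i > 0) hit <- hit + 1
    first <- NA
    for (k in seq_len(K)) if (row[k] == 1) { first <- k; break }
    if (!is.na(first)) rr <- rr + 1 / first
    if (n_i > 0) {
      s <- 0
      for (k in seq_len(K)) {
        if (row[k] == 1) {
          rel <- 0
          for (j in seq_len(k)) rel <- rel + row[j]
          s <- s + rel / k
        }
      }
      ap <- ap + s / n_i
    }
    if (n_i > 0) {
      dcg <- 0; ideal <- 0
      for (k in seq_len(K)) dcg <- dcg + row[k] / log2(k + 1)
      for (k in seq_len(n_i)) ideal <- ideal + 1 / log2(k + 1)
      ndcg <- ndcg + dcg / ideal
    }
  }
  c(hit = hit / N, mrr = rr / N, map = ap / N, mndcg = ndcg / N)
}

random_relevance <- function(N, K, cap = 3) {
  R <- matrix(0L, N, K)
  for (i in seq_len(N)) {
    n_rel <- sample(0:cap, 1)
    if (n_rel > 0 && n_rel <= K)
      R[i, sample.int(K, n_rel)] <- 1L
  }
  structure(list(R = R, n_iK = rowSums(R), cap = rep(cap, N),
                 missing = rowSums(R) == 0, K = K, N = N),
            class = "relevance_matrix")
}

# choose()-based enumeration oracle for Fisher's exact test
oracle_fisher <- function(a, b, c, d, alternative) {
  m <- a + c; n <- b + d; k <- a + b
  if (m == 0 || n == 0 || k == 0 || m + n - k == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  if (alternative == "greater") sum(probs[support >= a])
  else sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
}

best_rank_of <- function(ranking, tr) {
  r <- ranking$rank[ranking$tr_name == tr]
  if (length(r) == 0) Inf else min(r)
}
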