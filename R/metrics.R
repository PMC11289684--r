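# The ranking-evaluation framework: relevance matrices and the four metrics
# (hit rate, MRR, MAP, mean NDCG) at a threshold K, plus percentile hits and
# missing-TR accounting. Conventions for the undefined corners (no relevant
# term above K) give zero contribution, which keeps MRR_K <= H_K.

#' Build the relevance matrix for a set of ranking lists
#'
#' Entry `R[i, k] = 1` iff the k-th ranked term of list i names the list's
#' true (perturbed) TR; per-dataset rankings match on `tr_name` regardless
#' of `dataset_id`, so a list can contain several relevant terms. Lists
#' shorter than K are zero-padded.
#'
#' @param rankings List of [ranking_list()] objects.
#' @param truth Character vector of true TR labels, parallel to `rankings`.
#' @param K Rank threshold (>= 1).
#' @return A list with class `"relevance_matrix"`: binary `R` (N x K),
#'   `n_iK` (relevant count per list), `cap` (number of terms naming the
#'   true TR anywhere in the list), `missing` (true TR absent entirely),
#'   `K`, `N`.
#' @export
build_relevance <- function(rankings, truth, K) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  N <- length(rankings)
  if (length(truth) != N || anyNA(truth))
    stop("truth label required for every ranking list")
  R <- matrix(0L, N, K)
  cap <- integer(N)
  missing <- logical(N)
  for (i in seq_len(N)) {
    tr <- rankings[[i]]$tr_name
    cap[i] <- sum(tr == truth[i])
    missing[i] <- cap[i] == 0L
    top <- head(tr, K)
    R[i, seq_along(top)] <- as.integer(top == truth[i])
  }
  structure(list(R = R, n_iK = rowSums(R), cap = cap, missing = missing,
                 K = K, N = N),
            class = "relevance_matrix")
}

#' Hit rate at K
#'
#' Fraction of ranking lists with at least one relevant term above the
#' threshold: `H_K = mean(n_iK > 0)`.
#'
#' @param R A [build_relevance()] matrix.
#' @return `H_K` in \[0, 1\].
#' @export
hit_rate <- function(R) {
  mean(R$n_iK > 0)
}

#' Mean reciprocal rank at K
#'
#' `MRR_K = mean(1 / k_i*)` with `k_i*` the first relevant position; lists
#' with no relevant term above K contribute 0.
#'
#' @inheritParams hit_rate
#' @return `MRR_K` in \[0, 1\].
#' @export
mrr <- function(R) {
  rr <- apply(R$R, 1, function(row) {
    k <- which(row == 1L)
    if (length(k) == 0) 0 else 1 / k[1]
  })
  mean(rr)
}

#' Mean average precision at K
#'
#' Per list, precision `P_i(k) = (# relevant in top k) / k` is accumulated
#' at relevant positions only, summed and divided by `n_iK`; lists with
#' `n_iK = 0` contribute 0.
#'
#' @inheritParams hit_rate
#' @return `MAP_K` in \[0, 1\].
#' @export
map_at_k <- function(R) {
  ap <- apply(R$R, 1, function(row) {
    n <- sum(row)
    if (n == 0) return(0)
    ks <- which(row == 1L)
    sum(cumsum(row)[ks] / ks) / n
  })
  mean(ap)
}

#' Mean normalized discounted cumulative gain at K
#'
#' `DCG = sum_k R_ik / log2(k + 1)` normalized by the ideal DCG with all
#' `n_iK` relevant terms packed at the top; `n_iK = 0` lists contribute 0.
#'
#' @inheritParams hit_rate
#' @return `mNDCG_K` in \[0, 1\].
#' @export
mndcg <- function(R) {
  disc <- 1 / log2(seq_len(R$K) + 1)
  ndcg <- apply(R$R, 1, function(row) {
    n <- sum(row)
    if (n == 0) return(0)
    sum(row * disc) / sum(disc[seq_len(n)])
  })
  mean(ndcg)
}

# best (minimum) rank of the true TR in one ranking list; Inf when absent
best_tr_rank <- function(ranking, tr) {
  r <- ranking$rank[ranking$tr_name == tr]
  if (length(r) == 0) Inf else min(r)
}

#' Count lists ranking the true TR within a top percentile
#'
#' A list counts when the true TR's best rank is `<= ceiling(q * L)`, where
#' L is the list length.
#'
#' @param rankings List of [ranking_list()] objects.
#' @param truth True TR labels.
#' @param q Percentile as a fraction in (0, 1\].
#' @return Integer count.
#' @export
percentile_hits <- function(rankings, truth, q) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  sum(vapply(seq_along(rankings), function(i) {
    L <- nrow(rankings[[i]])
    best_tr_rank(rankings[[i]], truth[i]) <= ceiling(q * L)
  }, logical(1)))
}

#' Count lists whose true TR never appears
#'
#' @inheritParams percentile_hits
#' @return Integer count of missing-TR lists.
#' @export
missing_trs <- function(rankings, truth) {
  sum(vapply(seq_along(rankings), function(i)
    !truth[i] %in% rankings[[i]]$tr_name, logical(1)))
}

#' Full metric report
#'
#' All four ranking metrics at each threshold K, percentile hit counts and
#' the missing-TR count, in long format.
#'
#' @param rankings List of [ranking_list()] objects.
#' @param truth True TR labels, parallel to `rankings`.
#' @param K Integer vector of thresholds (default `c(10, 50, 100)`).
#' @param percentiles Fractions for percentile hits (default 1%, 5%, 10%).
#' @return A data.frame `metric`, `K`, `value` (percentile rows use the
#'   fraction in `K`).
#' @export
metric_report <- function(rankings, truth, K = c(10L, 50L, 100L),
                          percentiles = c(0.01, 0.05, 0.10)) {
  rows <- do.call(rbind, lapply(K, function(k) {
    R <- build_relevance(rankings, truth, k)
    data.frame(metric = c("hit_rate", "mrr", "map", "mndcg"), K = k,
               value = c(hit_rate(R), mrr(R), map_at_k(R), mndcg(R)),
               stringsAsFactors = FALSE)
  }))
  prows <- do.call(rbind, lapply(percentiles, function(q)
    data.frame(metric = "percentile_hits", K = q,
               value = percentile_hits(rankings, truth, q),
               stringsAsFactors = FALSE)))
  rbind(rows, prows,
        data.frame(metric = "missing_trs", K = NA_real_,
                   value = missing_trs(rankings, truth),
                   stringsAsFactors = FALSE))
}

#' Input-size sensitivity sweep
#'
#' Runs a ranker over case sets of increasing input size G and tabulates
#' all metrics per G, mirroring the degradation expected when noisier genes
#' enter the query.
#'
#' @param cases_by_G Named list (names = G) of case lists.
#' @param ranker Function `(case) -> ranking_list`.
#' @param K Thresholds.
#' @param percentiles Percentile fractions.
#' @return Long data.frame with columns `G`, `metric`, `K`, `value`.
#' @export
sensitivity_sweep <- function(cases_by_G, ranker, K = c(10L, 50L, 100L),
                              percentiles = c(0.01, 0.05, 0.10)) {
  do.call(rbind, lapply(names(cases_by_G), function(g) {
    cases <- cases_by_G[[g]]
    rankings <- lapply(cases, ranker)
    truth <- vapply(cases, `[[`, "", "true_tr")
    cbind(G = as.numeric(g),
          metric_report(rankings, truth, K, percentiles))
  }))
}
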