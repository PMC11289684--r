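# Pairwise method combination, multi-dataset bias testing with Stouffer
# integration, and the cutoff-sensitivity harness. TR-level rank = best
# (minimum) rank across that TR's datasets throughout.

# best rank per TR as a named vector (datasets collapsed)
tr_best_ranks <- function(ranking) {
  r <- tapply(ranking$rank, ranking$tr_name, min)
  setNames(as.numeric(r), names(r))
}

#' Jaccard similarity of two methods' top-K TRs
#'
#' Rankings are collapsed to TR level (best rank) first; the index is
#' `|A ∩ B| / |A ∪ B|` over the two top-K TR sets. Two empty sets are
#' defined as identical (index 1).
#'
#' @param ranking_a,ranking_b [ranking_list()] objects.
#' @param K Top-set size.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_topk <- function(ranking_a, ranking_b, K) {
  if (K < 1) stop("K must be >= 1")
  topk <- function(rk) {
    br <- sort(tr_best_ranks(rk))
    names(br)[seq_len(min(K, length(br)))]
  }
  a <- topk(ranking_a)
  b <- topk(ranking_b)
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Combine two methods' rankings case by case
#'
#' Per case, the combined rank of the true TR is the better (minimum) of
#' its best ranks in the two lists; hit counts, hit rate and MRR are then
#' computed on the combined ranks at each K. By construction the combined
#' metrics dominate both individual methods'.
#'
#' @param rankings_a,rankings_b Parallel lists of [ranking_list()] objects
#'   (same cases, same order).
#' @param truth True TR labels per case.
#' @param K Integer vector of thresholds.
#' @return A list: `combined_rank` (per case), and a data.frame `by_K` with
#'   `K`, `hits` (union top-K count), `hit_rate`, `mrr`.
#' @export
combine_pair <- function(rankings_a, rankings_b, truth,
                         K = c(10L, 50L, 100L)) {
  N <- length(rankings_a)
  if (length(rankings_b) != N || length(truth) != N)
    stop("rankings_a, rankings_b and truth must be parallel")
  ra <- vapply(seq_len(N), function(i)
    best_tr_rank(rankings_a[[i]], truth[i]), 0)
  rb <- vapply(seq_len(N), function(i)
    best_tr_rank(rankings_b[[i]], truth[i]), 0)
  comb <- pmin(ra, rb)
  by_K <- do.call(rbind, lapply(K, function(k)
    data.frame(K = k, hits = sum(comb <= k),
               hit_rate = mean(comb <= k),
               mrr = mean(ifelse(comb <= k, 1 / comb, 0)))))
  list(combined_rank = comb, rank_a = ra, rank_b = rb, by_K = by_K)
}

#' Multi-dataset bias test for one ranking list
#'
#' One-sided Wilcoxon rank-sum test of whether the deeply profiled TRs
#' (`multi_trs`) receive better (smaller) best ranks than the
#' single-dataset TRs. TRs absent from the ranking are assigned rank L + 1
#' with a warning. Exact p for small groups, normal approximation with tie
#' correction otherwise.
#'
#' @param ranking A [ranking_list()].
#' @param multi_trs,single_trs Character vectors of TR names (non-empty).
#' @return The one-sided p-value `p_i`.
#' @export
bias_test <- function(ranking, multi_trs, single_trs) {
  if (length(multi_trs) == 0 || length(single_trs) == 0)
    stop("both TR groups must be non-empty")
  br <- tr_best_ranks(ranking)
  L <- nrow(ranking)
  get_ranks <- function(trs) {
    r <- br[trs]
    if (anyNA(r)) {
      warning(sum(is.na(r)), " TR(s) absent from the ranking; assigned L+1")
      r[is.na(r)] <- L + 1
    }
    unname(r)
  }
  rank_sum_test(get_ranks(multi_trs), get_ranks(single_trs),
                alternative = "less")
}

#' Multi-dataset bias analysis over many ranking lists
#'
#' Applies [bias_test()] to each list (excluding cases whose perturbation
#' target is one of the selected TRs, so every remaining query behaves as a
#' random set with respect to the selection) and integrates the p-values by
#' Stouffer's Z-score method.
#'
#' @param rankings List of [ranking_list()] objects.
#' @param truth Optional true TR labels, used to exclude lists whose target
#'   is a selected TR.
#' @param multi_trs,single_trs TR groups.
#' @return A list with class `"bias_result"`: `p_i`, `Z_i`, `Z_c`, `p_c`,
#'   `I` (number of lists used), `excluded`.
#' @export
bias_analysis <- function(rankings, multi_trs, single_trs, truth = NULL) {
  keep <- rep(TRUE, length(rankings))
  if (!is.null(truth))
    keep <- !(truth %in% c(multi_trs, single_trs))
  used <- rankings[keep]
  if (length(used) == 0) stop("no ranking lists left after exclusion")
  p_i <- vapply(used, bias_test, 0, multi_trs = multi_trs,
                single_trs = single_trs)
  st <- stouffer_combine(p_i)
  structure(list(p_i = unname(p_i), Z_i = unname(st$Z_i), Z_c = st$Z_c,
                 p_c = st$p_c, I = length(p_i),
                 excluded = sum(!keep)),
            class = "bias_result")
}

#' @export
print.bias_result <- function(x, ...) {
  cat("<bias_result> I = ", x$I, " lists, Z_c = ",
      formatC(x$Z_c, digits = 3, format = "f"), ", p_c = ",
      formatC(x$p_c, digits = 3, format = "g"),
      " (", x$excluded, " excluded)\n", sep = "")
  invisible(x)
}

#' Cutoff-sensitivity harness
#'
#' Re-runs a window- or nearest-gene library workflow (one-sided Fisher
#' ranking) across a grid of cutoff values and records each case's true-TR
#' best rank, exposing how strongly the hard cutoff moves individual TR
#' ranks.
#'
#' @param datasets List of [peak_dataset()] objects.
#' @param annotation A [gene_annotation()].
#' @param cases List of [query_case()] objects.
#' @param cutoff_grid Numeric vector: window half-widths (bp) for
#'   `mode = "window"`, retained gene counts for `mode = "nearest"`.
#' @param mode `"window"` or `"nearest"`.
#' @param background Gene universe (default: all annotation symbols).
#' @return Data.frame `case_id`, `true_tr`, `cutoff`, `rank` (true TR's
#'   best rank; `Inf` when absent), |cases| x |grid| rows.
#' @export
cutoff_sensitivity <- function(datasets, annotation, cases, cutoff_grid,
                               mode = c("window", "nearest"),
                               background = annotation$symbol) {
  mode <- match.arg(mode)
  if (length(cutoff_grid) == 0) stop("cutoff_grid must be non-empty")
  do.call(rbind, lapply(cutoff_grid, function(cut) {
    lib <- if (mode == "window")
      build_target_library(datasets, annotation, "window", window = cut)
    else
      build_target_library(datasets, annotation, "nearest", n_genes = cut)
    rankings <- rank_library_cases(lib, cases, background)
    data.frame(
      case_id = vapply(cases, `[[`, "", "case_id"),
      true_tr = vapply(cases, `[[`, "", "true_tr"),
      cutoff = cut,
      rank = vapply(seq_along(cases), function(i)
        best_tr_rank(rankings[[i]], cases[[i]]$true_tr), 0),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Top-K frequency counter
#'
#' How often each TR appears in the top K across many ranking lists — the
#' generic counter behind "favorite TR" summaries.
#'
#' @param rankings List of [ranking_list()] objects.
#' @param K Threshold.
#' @return Data.frame `tr_name`, `count`, sorted decreasing.
#' @export
topk_frequency <- function(rankings, K = 10L) {
  tabs <- table(unlist(lapply(rankings, function(rk)
    unique(rk$tr_name[rk$rank <= K]))))
  df <- data.frame(tr_name = names(tabs), count = as.integer(tabs),
                   stringsAsFactors = FALSE)
  df[order(-df$count, df$tr_name), , drop = FALSE]
}
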