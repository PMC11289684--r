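# Proximal-elements-centric rankers. promoter_proportion_test emulates the
# ChIP-Atlas idea: does this dataset place a higher proportion of its peaks
# in query-gene promoters than a reference does? ks_rank emulates the MAGIC
# idea: per-gene maximum peak signal, compared between query and background
# eCDFs by a two-sample K-S test with a top-5%-signal scaling factor.

# count peaks falling in query-gene promoters vs background-only-gene
# promoters (a peak overlapping both kinds counts as query; peaks in
# neither are dropped)
classify_promoter_peaks <- function(peaks, annotation, query, background,
                                    upstream, downstream, proms = NULL) {
  if (is.null(proms))
    proms <- promoter_pair_granges(annotation, query, background,
                                   upstream, downstream)
  p_gr <- peaks_granges(peaks)
  in_q <- countOverlaps(p_gr, proms$query) > 0
  in_b <- countOverlaps(p_gr, proms$bg) > 0
  c(query = sum(in_q), bg = sum(in_b & !in_q))
}

promoter_pair_granges <- function(annotation, query, background,
                                  upstream, downstream) {
  bg_only <- setdiff(background, query)
  q_ann <- annotation[annotation$symbol %in% query, , drop = FALSE]
  b_ann <- annotation[annotation$symbol %in% bg_only, , drop = FALSE]
  list(query = promoter_granges(q_ann, upstream, downstream),
       bg = promoter_granges(b_ann, upstream, downstream))
}

#' Promoter-proportion enrichment test
#'
#' Classifies every peak of a dataset as lying inside a query-gene promoter
#' window, inside a background-only-gene promoter window, or neither, and
#' tests the dataset's (query : background) promoter-peak split against a
#' reference split with Fisher's exact test. The default reference is the
#' pooled peaks of all datasets; `reference = "genes"` instead compares
#' against the (|query| : |background - query|) gene-count split.
#'
#' @param peaks A [peak_dataset()].
#' @param annotation A [gene_annotation()].
#' @param query,background Gene sets (query must be inside background).
#' @param upstream,downstream Strand-aware promoter window in bp (defaults
#'   5 kb upstream, 0.5 kb downstream of the TSS).
#' @param alternative `"two.sided"` (default, as deployed in practice) or
#'   `"greater"`.
#' @param reference Pooled reference peaks (a data.frame of peaks, e.g.
#'   `pool_peaks(datasets)`), or `"genes"`.
#' @return The Fisher p-value; attribute `"counts"` carries the 2x2 cells.
#' @export
promoter_proportion_test <- function(peaks, annotation, query, background,
                                     upstream = 5000, downstream = 500,
                                     alternative = c("two.sided", "greater"),
                                     reference = "genes") {
  alternative <- match.arg(alternative)
  if (upstream <= 0) stop("promoter window must be positive")
  if (nrow(peaks$peaks) == 0) {
    warning("dataset ", peaks$dataset_id, " has no peaks; p = 1")
    return(structure(1, counts = c(0, 0, 0, 0)))
  }
  cnt <- classify_promoter_peaks(peaks$peaks, annotation, query, background,
                                 upstream, downstream)
  ref <- if (is.character(reference) && identical(reference, "genes")) {
    c(query = length(query), bg = length(setdiff(background, query)))
  } else {
    classify_promoter_peaks(reference, annotation, query, background,
                            upstream, downstream)
  }
  p <- fisher_exact(cnt[["query"]], cnt[["bg"]], ref[["query"]], ref[["bg"]],
                    alternative = alternative)
  structure(p, counts = c(cnt, ref))
}

#' Pool the peaks of many datasets
#' @param datasets List of [peak_dataset()] objects.
#' @return A single peak data.frame.
#' @export
pool_peaks <- function(datasets) {
  do.call(rbind, lapply(datasets, `[[`, "peaks"))
}

#' Promoter-proportion ranking over all datasets
#'
#' Runs [promoter_proportion_test()] per dataset against the pooled-peaks
#' reference and ranks ascending by p (BH q-values across datasets).
#'
#' @inheritParams promoter_proportion_test
#' @param datasets List of [peak_dataset()] objects.
#' @return A [ranking_list()].
#' @export
chipatlas_rank <- function(datasets, annotation, query, background,
                           upstream = 5000, downstream = 500,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (inherits(query, "query_case")) query <- query$genes
  # build promoter windows and classify the pooled reference once
  proms <- promoter_pair_granges(annotation, query, background,
                                 upstream, downstream)
  ref <- classify_promoter_peaks(pool_peaks(datasets), annotation, query,
                                 background, upstream, downstream, proms)
  p <- vapply(datasets, function(ds) {
    if (nrow(ds$peaks) == 0) {
      warning("dataset ", ds$dataset_id, " has no peaks; p = 1")
      return(1)
    }
    cnt <- classify_promoter_peaks(ds$peaks, annotation, query, background,
                                   upstream, downstream, proms)
    fisher_exact(cnt[["query"]], cnt[["bg"]], ref[["query"]], ref[["bg"]],
                 alternative = alternative)
  }, 0)
  rank_datasets(data.frame(
    dataset_id = vapply(datasets, `[[`, "", "dataset_id"),
    tr_name = vapply(datasets, `[[`, "", "tr_name"),
    p = p, stringsAsFactors = FALSE))
}

#' Per-gene maximum peak signal
#'
#' Assigns each annotated gene the highest signal among the peaks
#' overlapping its symmetric surrounding region `[tss - window, tss +
#' window)`; genes with no overlapping peak get 0.
#'
#' @inheritParams promoter_proportion_test
#' @param window Half-width of the surrounding region (bp).
#' @return Named numeric vector over all annotation genes (a
#'   gene-signal profile).
#' @export
gene_max_signal <- function(peaks, annotation, window = 5000) {
  if (window <= 0) stop("window must be positive")
  pk <- if (inherits(peaks, "peak_dataset")) peaks$peaks else peaks
  prof <- fast_max_signal(pk, tss_index(annotation), nrow(annotation),
                          window)
  setNames(prof, annotation$symbol)
}

# ratio of top-5% mean signals (query vs background), ceiling count >= 1,
# clamped to [1e-3, 1e3]
signal_scaling_factor <- function(q_sig, b_sig, top = 0.05,
                                  clamp = c(1e-3, 1e3)) {
  top_mean <- function(v) {
    n <- max(1L, ceiling(top * length(v)))
    mean(sort(v, decreasing = TRUE)[seq_len(n)])
  }
  mq <- top_mean(q_sig)
  mb <- top_mean(b_sig)
  if (mq == mb) return(1)
  ratio <- if (mb == 0) clamp[2] else mq / mb
  min(max(ratio, clamp[1]), clamp[2])
}

#' Max-signal eCDF ranking (two-sample K-S)
#'
#' For each dataset's gene-signal profile, compares the query genes' signal
#' values against the background-minus-query values with a two-sample
#' Kolmogorov-Smirnov test (exact when both groups have <= 25 values and no
#' ties, asymptotic otherwise), BH-corrects across datasets, and scores each
#' dataset as `-log10(q)` times the top-5%-signal scaling factor. Ranked
#' descending by score.
#'
#' @param profiles Named list of gene-signal profiles (from
#'   [gene_max_signal()]), one per dataset.
#' @param tr_names Character vector of TR names parallel to `profiles`.
#' @param query,background Gene sets.
#' @return A [ranking_list()]; extra column `D` holds the K-S statistics.
#' @export
ks_rank <- function(profiles, tr_names, query, background) {
  if (inherits(query, "query_case")) query <- query$genes
  bg_only <- setdiff(background, query)
  if (length(query) < 2 || length(bg_only) < 2)
    stop("need >= 2 query genes and >= 2 background-only genes")
  res <- lapply(profiles, function(prof) {
    x <- prof[query]
    y <- prof[bg_only]
    if (max(x) == min(x) && max(y) == min(y) && max(x) == max(y))
      return(list(D = 0, p = 1, s = 1))
    exact <- length(x) <= 25 && length(y) <= 25 && !anyDuplicated(c(x, y))
    ks <- suppressWarnings(ks.test(x, y, exact = exact))
    list(D = unname(ks$statistic), p = unname(ks$p.value),
         s = signal_scaling_factor(x, y))
  })
  p <- vapply(res, `[[`, 0, "p")
  q <- bh_adjust(p)
  score <- -log10(pmax(q, 1e-300)) * vapply(res, `[[`, 0, "s")
  ids <- names(profiles)
  ord <- order(-score, ids)
  rl <- ranking_list(data.frame(
    tr_name = tr_names[ord], dataset_id = ids[ord], score = score[ord],
    p = p[ord], q = q[ord], stringsAsFactors = FALSE))
  rl$D <- vapply(res, `[[`, 0, "D")[ord]
  rl
}

#' MAGIC-style ranking of peak datasets
#'
#' Convenience wrapper: builds [gene_max_signal()] profiles for every
#' dataset and ranks them with [ks_rank()].
#'
#' @inheritParams chipatlas_rank
#' @param window Surrounding-region half-width (bp).
#' @return A [ranking_list()].
#' @export
magic_rank <- function(datasets, annotation, query, background,
                       window = 5000) {
  tidx <- tss_index(annotation)
  profiles <- lapply(datasets, function(ds)
    setNames(fast_max_signal(ds$peaks, tidx, nrow(annotation), window),
             annotation$symbol))
  names(profiles) <- vapply(datasets, `[[`, "", "dataset_id")
  ks_rank(profiles, vapply(datasets, `[[`, "", "tr_name"), query, background)
}
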