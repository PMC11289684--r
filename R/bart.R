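# BART-style ranking: score a genome-wide candidate-site universe (DHS-like)
# by a weighted combination of the selected epigenome tracks, measure how
# well those scores predict each TR dataset's peak presence (AUC), compare
# each TR's AUCs against the pooled AUC distribution (Wilcoxon), standardize
# the top AUC against a null calibrated on random gene sets, and average the
# three component ranks.

#' Candidate-site universe from signal tracks
#'
#' The reduced union of all track peak intervals stands in for a
#' genome-wide DHS collection.
#'
#' @param tracks List of [signal_track()] objects.
#' @return A 0-based half-open interval data.frame (`chrom`, `start`, `end`).
#' @export
dhs_sites <- function(tracks) {
  gr <- reduce(peaks_granges(pool_peaks(tracks)))
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr) - 1L, end = end(gr),
             stringsAsFactors = FALSE)
}

# sites x tracks matrix of max overlapping-peak signal (0 when none)
site_signal_matrix <- function(sites, tracks) {
  s_gr <- peaks_granges(sites)
  vapply(tracks, function(tk) {
    v <- numeric(nrow(sites))
    hits <- findOverlaps(s_gr, peaks_granges(tk$peaks))
    if (length(hits)) {
      mx <- tapply(tk$peaks$signal[subjectHits(hits)], queryHits(hits), max)
      v[as.integer(names(mx))] <- as.numeric(mx)
    }
    v
  }, numeric(nrow(sites)))
}

# strict component ranks 1..n, ties broken lexicographically by name
rank_with_names <- function(key, nm) {
  r <- integer(length(key))
  r[order(key, nm)] <- seq_along(key)
  r
}

#' BART-style TR ranking
#'
#' @param datasets List of [peak_dataset()] objects.
#' @param tracks List of [signal_track()] objects (the selection
#'   compendium; also defines the candidate-site universe).
#' @param annotation A [gene_annotation()].
#' @param query,background Gene sets.
#' @param max_k Stepwise selection cap.
#' @param n_null_sets Random gene sets used to calibrate the TR-wise
#'   mean/sd of the top AUC (default 100).
#' @param seed Integer seed for the null calibration.
#' @param window,half_life RP parameters for the selection step.
#' @return A [ranking_list()] with one term per TR; extra columns
#'   `max_auc`, `wilcox_p`, `z` and the three component ranks.
#' @export
bart_rank <- function(datasets, tracks, annotation, query, background,
                      max_k = 10L, n_null_sets = 100L, seed = 1L,
                      window = 1e4, half_life = 1000) {
  if (inherits(query, "query_case")) query <- query$genes
  if (length(datasets) < 2) stop("need >= 2 TR datasets")
  set.seed(seed)
  rp <- rp_matrix(tracks, annotation, window, "exponential", half_life)
  rownames(rp) <- annotation$symbol
  sites <- dhs_sites(tracks)
  if (nrow(sites) == 0) stop("empty candidate-site universe")
  sig <- site_signal_matrix(sites, tracks)
  colnames(sig) <- colnames(rp)
  s_gr <- peaks_granges(sites)
  # site labels per dataset are query-independent: compute once
  pos_sets <- lapply(datasets, function(ds)
    which(countOverlaps(s_gr, peaks_granges(ds$peaks)) > 0))
  ds_tr <- vapply(datasets, `[[`, "", "tr_name")
  n_sites <- nrow(sites)

  aucs_for_query <- function(q) {
    model <- select_predictive_samples(rp, annotation$symbol %in% q, max_k)
    # weight each selected track's site signal on the same scale the
    # logistic coefficients were fitted on (standardized log1p); the
    # centering term shifts every site equally and cannot change an AUC
    scores <- drop(log1p(sig[, model$samples, drop = FALSE]) %*%
                     (model$coefficients[-1] / model$scale))
    r <- rank(scores)
    vapply(seq_along(datasets), function(i) {
      np <- length(pos_sets[[i]])
      nn <- n_sites - np
      if (np == 0 || nn == 0) return(NA_real_)
      (sum(r[pos_sets[[i]]]) - np * (np + 1) / 2) / (np * nn)
    }, 0)
  }

  obs_auc <- aucs_for_query(query)
  if (anyNA(obs_auc)) {
    warning(sum(is.na(obs_auc)),
            " dataset(s) overlap no candidate site; AUC set to 0.5")
    obs_auc[is.na(obs_auc)] <- 0.5
  }
  trs <- sort(unique(ds_tr))
  max_auc <- vapply(trs, function(tr) max(obs_auc[ds_tr == tr]), 0)
  wilcox_p <- vapply(trs, function(tr)
    rank_sum_test(obs_auc[ds_tr == tr], obs_auc, alternative = "greater"), 0)

  null_max <- matrix(NA_real_, n_null_sets, length(trs),
                     dimnames = list(NULL, trs))
  for (s in seq_len(n_null_sets)) {
    qn <- sample(background, length(query))
    a <- aucs_for_query(qn)
    a[is.na(a)] <- 0.5
    null_max[s, ] <- vapply(trs, function(tr) max(a[ds_tr == tr]), 0)
  }
  z <- (max_auc - colMeans(null_max)) /
    pmax(apply(null_max, 2, sd), 1e-9)

  r_auc <- rank_with_names(-max_auc, trs)
  r_p <- rank_with_names(wilcox_p, trs)
  r_z <- rank_with_names(-z, trs)
  avg <- (r_auc + r_p + r_z) / 3
  ord <- order(avg, trs)
  rl <- ranking_list(data.frame(
    tr_name = trs[ord], dataset_id = NA_character_,
    score = -avg[ord], p = wilcox_p[ord], q = bh_adjust(wilcox_p)[ord],
    stringsAsFactors = FALSE))
  rl$max_auc <- max_auc[ord]
  rl$z <- z[ord]
  rl$rank_auc <- r_auc[ord]
  rl$rank_p <- r_p[ord]
  rl$rank_z <- r_z[ord]
  rl$avg_rank <- avg[ord]
  rl
}
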