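# Distal-elements-inclusive machinery: the regulatory-potential (RP) model,
# forward-stepwise logistic selection of predictive epigenome tracks,
# in-silico deletion (ISD) of a TR's binding loci, and the Lisa-style
# ranking that combines Wilcoxon tests on delta-RP and peak-RP by the
# Cauchy combination test.

#' Regulatory potential of every gene
#'
#' `RP(g) = sum over peaks with midpoint distance d <= window of
#' signal * w(d)`, with `w = 1` (uniform) or `w = 2^(-d/half_life)`
#' (exponential decay; a peak exactly one half-life away contributes half
#' its signal).
#'
#' @param x A [signal_track()], [peak_dataset()] or raw peak data.frame.
#' @param annotation A [gene_annotation()].
#' @param window Half-width (bp) of the surrounding region (default 10 kb).
#' @param decay `"exponential"` (default) or `"uniform"`.
#' @param half_life Decay half-life in bp (default 1 kb).
#' @return Named numeric vector of RP scores over all annotation genes.
#' @export
compute_rp <- function(x, annotation, window = 1e4,
                       decay = c("exponential", "uniform"),
                       half_life = 1000) {
  decay <- match.arg(decay)
  if (window <= 0) stop("window must be positive")
  if (decay == "exponential" && half_life <= 0)
    stop("half_life must be positive")
  peaks <- if (is.data.frame(x)) x else x$peaks
  ctb <- rp_contributions(peaks, annotation, window, decay, half_life)
  rp <- setNames(numeric(nrow(annotation)), annotation$symbol)
  if (nrow(ctb)) {
    agg <- rowsum(ctb$contrib, ctb$gene_idx)
    rp[as.integer(rownames(agg))] <- agg[, 1]
  }
  rp
}

# (peak index, gene index, signal * weight) triplets for all peak/gene
# pairs within the RP window; the sparse backbone for fast ISD deltas
rp_contributions <- function(peaks, annotation, window, decay, half_life) {
  if (nrow(peaks) == 0)
    return(data.frame(peak = integer(), gene_idx = integer(),
                      contrib = numeric()))
  hits <- findOverlaps(tss_window_granges(annotation, window),
                       midpoint_granges(peaks))
  gi <- queryHits(hits)
  pj <- subjectHits(hits)
  d <- abs(peak_midpoint(peaks)[pj] - annotation$tss[gi])
  keep <- d <= window
  gi <- gi[keep]; pj <- pj[keep]; d <- d[keep]
  w <- if (decay == "uniform") rep(1, length(d)) else 2^(-d / half_life)
  data.frame(peak = pj, gene_idx = gi, contrib = peaks$signal[pj] * w)
}

#' RP matrix over a track compendium
#'
#' @param tracks List of [signal_track()] objects.
#' @inheritParams compute_rp
#' @return genes x samples numeric matrix with attributes `assay` (per
#'   column) and the RP parameters.
#' @export
rp_matrix <- function(tracks, annotation, window = 1e4,
                      decay = c("exponential", "uniform"), half_life = 1000) {
  decay <- match.arg(decay)
  m <- vapply(tracks, compute_rp, numeric(nrow(annotation)),
              annotation = annotation, window = window, decay = decay,
              half_life = half_life)
  colnames(m) <- vapply(tracks, `[[`, "", "sample_id")
  structure(m, assay = setNames(vapply(tracks, `[[`, "", "assay"),
                                colnames(m)),
            window = window, decay = decay, half_life = half_life)
}

#' Forward-stepwise logistic selection of predictive samples
#'
#' Models query membership (gene in the input list: yes/no) as a function of
#' standardized `log1p(RP)` scores and greedily adds the sample minimizing
#' the AIC at each step, stopping when no sample improves the AIC or when
#' `max_k` samples are selected. Zero-variance samples are never candidates.
#' On complete separation the final coefficients come from a
#' ridge-penalized fit (with a warning).
#'
#' @param rp genes x samples RP matrix (from [rp_matrix()]).
#' @param membership Logical vector (or gene-symbol character vector) of
#'   query membership, aligned to `rownames(rp)`.
#' @param max_k Maximum number of selected samples.
#' @return A list with class `"selection_model"`: `samples` (ordered),
#'   `coefficients` (intercept first), `center`, `scale`, `aic_trace`,
#'   `ridge` flag, `assay` (per selected sample, when known).
#' @export
select_predictive_samples <- function(rp, membership, max_k = 10L) {
  if (ncol(rp) < 2) stop("need at least 2 samples")
  if (is.character(membership))
    membership <- rownames(rp) %in% membership
  y <- as.integer(membership)
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- log1p(rp)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  ok <- which(scl > 0)
  Z <- sweep(sweep(X[, ok, drop = FALSE], 2, ctr[ok]), 2, scl[ok], "/")
  sel <- integer(0)
  aic_trace <- AIC(glm(y ~ 1, family = binomial()))
  repeat {
    cands <- setdiff(seq_along(ok), sel)
    if (length(cands) == 0 || length(sel) >= max_k) break
    aics <- vapply(cands, function(j) {
      fit <- suppressWarnings(
        glm.fit(cbind(1, Z[, c(sel, j), drop = FALSE]), y,
                family = binomial()))
      fit$aic
    }, 0)
    best <- cands[which.min(aics)]
    # the first step always takes the best candidate (the model must use at
    # least one sample); later steps require an AIC improvement
    if (length(sel) == 0 ||
        min(aics) < aic_trace[length(aic_trace)] - 1e-8) {
      sel <- c(sel, best)
      aic_trace <- c(aic_trace, min(aics))
    } else break
  }
  final <- suppressWarnings(glm(y ~ Z[, sel, drop = FALSE],
                                family = binomial()))
  ridge <- !final$converged ||
    any(abs(predict(final, type = "link")) > 15)
  if (ridge) {
    warning("separation detected; falling back to ridge-penalized fit")
    Xr <- Z[, sel, drop = FALSE]
    pad <- ncol(Xr) == 1  # glmnet requires >= 2 columns
    if (pad) Xr <- cbind(Xr, 0)
    rf <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                         lambda = 1e-2, standardize = FALSE)
    cf <- as.numeric(coef(rf))
    if (pad) cf <- cf[1:2]
  } else {
    cf <- unname(coef(final))
  }
  samples <- colnames(Z)[sel]
  assay <- attr(rp, "assay")
  structure(
    list(samples = samples,
         coefficients = setNames(cf, c("(Intercept)", samples)),
         center = ctr[ok][sel], scale = scl[ok][sel],
         aic_trace = aic_trace, ridge = ridge,
         assay = if (!is.null(assay)) assay[samples] else NULL),
    class = "selection_model")
}

#' @export
print.selection_model <- function(x, ...) {
  cat("<selection_model> ", length(x$samples), " sample(s): ",
      paste(x$samples, collapse = ", "),
      if (x$ridge) " [ridge]" else "", "\n", sep = "")
  invisible(x)
}

# linear predictor of the fitted model for an RP matrix restricted to the
# selected samples (columns matched by name; missing -> error)
model_linear_predictor <- function(model, rp) {
  Z <- sweep(sweep(log1p(rp[, model$samples, drop = FALSE]), 2,
                   model$center), 2, model$scale, "/")
  drop(model$coefficients[1] +
         Z %*% model$coefficients[-1])
}

#' In-silico deletion of a TR's binding loci from a track
#'
#' Sets to zero the signal of every track peak that overlaps any peak of the
#' TR dataset extended by `flank` bp on both sides; all other peaks are
#' untouched.
#'
#' @param track A [signal_track()].
#' @param peaks A [peak_dataset()] (the TR's binding loci).
#' @param flank Extension (bp) applied to the TR peaks, >= 0.
#' @return The modified [signal_track()].
#' @export
in_silico_delete <- function(track, peaks, flank = 1000) {
  if (flank < 0) stop("flank must be >= 0")
  if (nrow(peaks$peaks) == 0 || nrow(track$peaks) == 0) return(track)
  tr_ext <- data.frame(chrom = peaks$peaks$chrom,
                       start = pmax(peaks$peaks$start - flank, 0),
                       end = peaks$peaks$end + flank)
  hit <- countOverlaps(peaks_granges(track$peaks), peaks_granges(tr_ext)) > 0
  track$peaks$signal[hit] <- 0
  track
}

#' Chromatin RP change under in-silico deletion
#'
#' @inheritParams in_silico_delete
#' @param annotation A [gene_annotation()].
#' @param window,decay,half_life RP parameters (see [compute_rp()]).
#' @return Data.frame per gene: `gene`, `rp_before`, `rp_after`, `delta`
#'   (`= before - after`, always >= 0).
#' @export
delta_rp <- function(track, peaks, annotation, flank = 1000, window = 1e4,
                     decay = c("exponential", "uniform"), half_life = 1000) {
  decay <- match.arg(decay)
  before <- compute_rp(track, annotation, window, decay, half_life)
  after <- compute_rp(in_silico_delete(track, peaks, flank), annotation,
                      window, decay, half_life)
  data.frame(gene = names(before), rp_before = as.numeric(before),
             rp_after = as.numeric(after),
             delta = as.numeric(before - after),
             stringsAsFactors = FALSE, row.names = NULL)
}

# deleted-peak index set of a track for one dataset (flank-extended overlap)
deleted_track_peaks <- function(track_peaks, dataset_peaks, flank) {
  tr_ext <- data.frame(chrom = dataset_peaks$chrom,
                       start = pmax(dataset_peaks$start - flank, 0),
                       end = dataset_peaks$end + flank)
  which(countOverlaps(peaks_granges(track_peaks), peaks_granges(tr_ext)) > 0)
}

#' Lisa-style TR-dataset ranking
#'
#' Selects predictive H3K27ac and DNase tracks by stepwise logistic
#' regression on chromatin RP, then scores every TR ChIP-seq dataset by
#' three one-sided Wilcoxon rank-sum tests (query greater than background)
#' on: the change of each assay's fitted linear predictor under in-silico
#' deletion of the dataset's peaks (delta-RP propagated through the model),
#' and the dataset's own peak-RP. The three p-values are combined by the
#' Cauchy combination test; datasets are ranked ascending by the combined p.
#'
#' @param datasets List of [peak_dataset()] objects.
#' @param tracks List of [signal_track()] objects (both assays present).
#' @param annotation A [gene_annotation()].
#' @param query,background Gene sets.
#' @param max_k Stepwise selection cap per assay.
#' @param window,half_life RP parameters (exponential decay).
#' @param flank ISD flank in bp.
#' @return A [ranking_list()] with extra columns `p_h3k27ac`, `p_dnase`,
#'   `p_peak`; attribute `"models"` holds the per-assay selection models.
#' @export
lisa_rank <- function(datasets, tracks, annotation, query, background,
                      max_k = 10L, window = 1e4, half_life = 1000,
                      flank = 1000) {
  if (inherits(query, "query_case")) query <- query$genes
  if (length(query) == 0) stop("query is empty")
  assays <- vapply(tracks, `[[`, "", "assay")
  if (!all(c("H3K27ac", "DNase") %in% assays))
    stop("need at least one H3K27ac and one DNase track")
  qmask <- annotation$symbol %in% query
  bmask <- annotation$symbol %in% setdiff(background, query)
  tidx <- tss_index(annotation)
  n_genes <- nrow(annotation)

  per_assay <- lapply(c(H3K27ac = "H3K27ac", DNase = "DNase"), function(as) {
    tr_sub <- tracks[assays == as]
    rp <- rp_matrix(tr_sub, annotation, window, "exponential", half_life)
    rownames(rp) <- annotation$symbol
    model <- select_predictive_samples(rp, qmask, max_k)
    sel_tracks <- tr_sub[match(model$samples, vapply(tr_sub, `[[`, "",
                                                     "sample_id"))]
    # per selected track: sparse peak->gene contributions and total RP
    ctbs <- lapply(sel_tracks, function(tk)
      rp_contributions(tk$peaks, annotation, window, "exponential",
                       half_life))
    rp_sel <- rp[, model$samples, drop = FALSE]
    list(model = model, tracks = sel_tracks, ctbs = ctbs, rp = rp_sel)
  })

  score_dataset <- function(ds) {
    # merged flank-extended binding loci of this dataset, indexed per chrom
    ext <- data.frame(chrom = ds$peaks$chrom,
                      start = pmax(ds$peaks$start - flank, 0),
                      end = ds$peaks$end + flank)
    midx <- merged_interval_index(reduce(peaks_granges(ext)))
    lp_assay <- vapply(per_assay, function(pa) {
      rp_after <- pa$rp
      for (j in seq_along(pa$tracks)) {
        del <- overlapping_peaks(pa$tracks[[j]]$peaks, midx)
        if (length(del) == 0) next
        ctb <- pa$ctbs[[j]]
        sub <- ctb[ctb$peak %in% del, , drop = FALSE]
        if (nrow(sub) == 0) next
        loss <- rowsum(sub$contrib, sub$gene_idx)
        gi <- as.integer(rownames(loss))
        rp_after[gi, j] <- pmax(rp_after[gi, j] - loss[, 1], 0)
      }
      d_lp <- model_linear_predictor(pa$model, pa$rp) -
        model_linear_predictor(pa$model, rp_after)
      rank_sum_test(d_lp[qmask], d_lp[bmask], alternative = "greater",
                    log_p = TRUE)
    }, 0)
    peak_rp <- fast_rp(ds$peaks, tidx, n_genes, window, "exponential",
                       half_life)
    lp_peak <- rank_sum_test(peak_rp[qmask], peak_rp[bmask],
                             alternative = "greater", log_p = TRUE)
    c(lp_assay, peak = lp_peak)
  }

  lps <- vapply(datasets, score_dataset, numeric(3))
  # combine on the log scale so saturated (astronomically significant)
  # datasets stay distinguishable
  combined_log <- apply(lps, 2, cauchy_combine_log)
  combined <- exp(combined_log)
  ids <- vapply(datasets, `[[`, "", "dataset_id")
  ord <- order(combined_log, ids)
  rl <- ranking_list(data.frame(
    tr_name = vapply(datasets, `[[`, "", "tr_name")[ord],
    dataset_id = ids[ord],
    score = -combined_log[ord] / log(10),
    p = combined[ord], q = bh_adjust(combined)[ord],
    stringsAsFactors = FALSE))
  rl$log_p <- combined_log[ord]
  rl$p_h3k27ac <- exp(lps[1, ord])
  rl$p_dnase <- exp(lps[2, ord])
  rl$p_peak <- exp(lps[3, ord])
  attr(rl, "models") <- lapply(per_assay, `[[`, "model")
  rl
}
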