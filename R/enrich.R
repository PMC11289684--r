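# Library-based ranking: Fisher enrichment of target-gene sets against a
# query / background split, with optional simulation-based z-score rank
# correction and per-TR integration of per-dataset ranks. Background default
# is the full annotated universe; the query is carved out of the background
# inside the 2x2 (rows: query vs background \ query).

#' Build the 2x2 enrichment table for one target set
#'
#' `a = |query ∩ target|`, `b = |query \\ target|`,
#' `c = |(background \\ query) ∩ target|`, `d = remainder`. Target genes
#' outside the background are ignored.
#'
#' @param target A `target_set` or character vector of target genes.
#' @param query Character vector of query genes; must be a subset of
#'   `background`.
#' @param background Character vector, the gene universe.
#' @return A [contingency_table()].
#' @export
build_contingency <- function(target, query, background) {
  genes <- if (inherits(target, "target_set")) target$genes else
    as.character(target)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  t_in_bg <- intersect(genes, background)
  a <- length(intersect(query, t_in_bg))
  b <- length(query) - a
  c <- length(t_in_bg) - a
  d <- length(background) - length(query) - c
  contingency_table(a, b, c, d)
}

# logical genes x datasets membership matrix for fast batch ranking
library_membership <- function(library, background) {
  m <- matrix(FALSE, length(background), length(library$sets),
              dimnames = list(background, names(library$sets)))
  for (j in seq_along(library$sets)) {
    idx <- match(library$sets[[j]]$genes, background)
    m[idx[!is.na(idx)], j] <- TRUE
  }
  m
}

#' Rank datasets by enrichment p-values
#'
#' Sorts ascending by `p` (or by `z` when present and `by = "z"`), ties
#' broken by `dataset_id`; assigns ranks 1..L and BH q-values across the
#' datasets of this run (one multiple-testing family per ranking).
#'
#' @param results Data.frame with columns `dataset_id`, `tr_name`, `p` and
#'   optionally `z`.
#' @param by Sort key, `"p"` (default) or `"z"`.
#' @return A [ranking_list()]; a `z` column is carried through if present.
#' @export
rank_datasets <- function(results, by = c("p", "z")) {
  by <- match.arg(by)
  if (nrow(results) == 0) stop("rank_datasets needs at least one result")
  if (by == "z" && is.null(results$z)) stop("no z column to rank by")
  results$q <- bh_adjust(results$p)
  key <- if (by == "z") results$z else results$p
  ord <- order(key, results$dataset_id)
  res <- results[ord, , drop = FALSE]
  rl <- ranking_list(data.frame(
    tr_name = res$tr_name, dataset_id = res$dataset_id,
    score = -log10(pmax(res$p, 1e-300)), p = res$p, q = res$q,
    stringsAsFactors = FALSE))
  if (!is.null(res$z)) rl$z <- res$z
  rl
}

#' Fisher-enrichment ranking of a target library
#'
#' For every dataset in the library, tests whether its target-gene set is
#' enriched with the query genes (relative to the background universe) and
#' ranks datasets by significance.
#'
#' @param library A `target_library`.
#' @param query Character vector of query genes (or a [query_case()]).
#' @param background Gene universe (character vector).
#' @param alternative `"greater"` (default, one-sided enrichment) or
#'   `"two.sided"`.
#' @param membership Optional precomputed [library] membership matrix (from
#'   repeated calls over many cases); built on the fly when `NULL`.
#' @return A [ranking_list()] with one term per dataset.
#' @export
rank_library <- function(library, query, background,
                         alternative = c("greater", "two.sided"),
                         membership = NULL) {
  alternative <- match.arg(alternative)
  if (inherits(query, "query_case")) query <- query$genes
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  if (is.null(membership)) membership <- library_membership(library, background)
  qidx <- match(query, background)
  a <- colSums(membership[qidx, , drop = FALSE])
  t_size <- colSums(membership)
  N <- length(background)
  k <- length(query)
  p <- if (alternative == "greater") {
    phyper_greater(a, t_size, N, k)
  } else {
    mapply(function(ai, ti) fisher_exact(ai, k - ai, ti - ai,
                                         N - k - (ti - ai),
                                         alternative = "two.sided"),
           a, t_size)
  }
  rank_datasets(data.frame(dataset_id = library$meta$dataset_id,
                           tr_name = library$meta$tr_name, p = as.numeric(p),
                           stringsAsFactors = FALSE))
}

#' Rank a library against many query cases
#'
#' Builds the membership matrix once and ranks each case; the fast path for
#' benchmark sweeps.
#'
#' @inheritParams rank_library
#' @param cases List of [query_case()] objects.
#' @return Named list of [ranking_list()] objects (by case_id).
#' @export
rank_library_cases <- function(library, cases, background,
                               alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  membership <- library_membership(library, background)
  out <- lapply(cases, function(cs)
    rank_library(library, cs, background, alternative, membership))
  names(out) <- vapply(cases, `[[`, "", "case_id")
  out
}

#' Simulation-based z-score rank correction
#'
#' Corrects Fisher-p ranks for gene-set-size bias by simulating random
#' queries of the same size: each dataset's observed rank is standardized
#' against its rank distribution under random queries,
#' `z = (observed - mean) / sd` (sd floored at 1e-9); negative z means
#' ranked better than expected.
#'
#' @inheritParams rank_library
#' @param n_sim Number of simulated random queries (>= 10).
#' @param seed Integer seed.
#' @return Data.frame `dataset_id`, `tr_name`, `p`, `observed_rank`,
#'   `expected_rank`, `sd`, `z` — suitable for `rank_datasets(..., by = "z")`.
#' @export
zscore_correction <- function(library, query, background, n_sim = 100L,
                              seed = 1L, membership = NULL) {
  if (n_sim < 10L) stop("n_sim must be >= 10")
  if (inherits(query, "query_case")) query <- query$genes
  set.seed(seed)
  if (is.null(membership)) membership <- library_membership(library, background)
  t_size <- colSums(membership)
  N <- length(background)
  k <- length(query)
  rank_of <- function(p) {
    ord <- order(p, library$meta$dataset_id)
    r <- integer(length(p)); r[ord] <- seq_along(p); r
  }
  obs_p <- phyper_greater(colSums(membership[match(query, background), ,
                                             drop = FALSE]), t_size, N, k)
  obs_rank <- rank_of(obs_p)
  sims <- vapply(seq_len(n_sim), function(s) {
    qidx <- sample.int(N, k)
    rank_of(phyper_greater(colSums(membership[qidx, , drop = FALSE]),
                           t_size, N, k))
  }, integer(ncol(membership)))
  mu <- rowMeans(sims)
  sdev <- apply(sims, 1, sd)
  data.frame(dataset_id = library$meta$dataset_id,
             tr_name = library$meta$tr_name, p = obs_p,
             observed_rank = obs_rank, expected_rank = mu, sd = sdev,
             z = (obs_rank - mu) / pmax(sdev, 1e-9),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Integrate per-dataset ranks into one rank per TR
#'
#' Summarizes each TR's dataset ranks by the best (minimum) or the
#' arithmetic mean rank, then re-ranks TRs by the summary (ties by
#' `tr_name`).
#'
#' @param ranking A per-dataset [ranking_list()].
#' @param mode `"best"` or `"mean"`.
#' @return A [ranking_list()] with one term per TR; `score` holds the
#'   negated summary rank, `p` the TR's best p-value.
#' @export
integrate_tr_ranks <- function(ranking, mode = c("best", "mean")) {
  mode <- match.arg(mode)
  fn <- if (mode == "best") min else mean
  summ <- tapply(ranking$rank, ranking$tr_name, fn)
  best_p <- tapply(ranking$p, ranking$tr_name, min)
  trs <- names(summ)
  ord <- order(as.numeric(summ), trs)
  ranking_list(data.frame(
    tr_name = trs[ord], dataset_id = NA_character_,
    score = -as.numeric(summ)[ord], p = as.numeric(best_p)[ord],
    stringsAsFactors = FALSE))
}
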