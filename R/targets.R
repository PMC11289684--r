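# Peak -> target-gene assignment: the three algorithms used by library-based
# rankers. window: any-overlap (>= 1 bp) of a peak with the symmetric
# half-open window [tss - w, tss + w). nearest: genes with the closest peak
# midpoints. density: distance-weighted peak aggregation with a top-quantile
# cutoff.

target_set <- function(dataset_id, tr_name, genes, method, params) {
  structure(
    list(dataset_id = dataset_id, tr_name = tr_name,
         genes = sort(unique(as.character(genes))),
         method = method, params = params),
    class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("<target_set> ", x$dataset_id, " (", x$method, "): ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Window-based target assignment
#'
#' A gene is a target iff at least one peak interval overlaps the symmetric
#' window `[tss - window, tss + window)` (0-based half-open; any overlap of
#' >= 1 bp counts).
#'
#' @param peaks A [peak_dataset()].
#' @param annotation A [gene_annotation()].
#' @param window Half-width of the TSS window in bp (> 0).
#' @return A `target_set`.
#' @export
assign_targets_window <- function(peaks, annotation, window) {
  if (window <= 0) stop("window must be positive")
  w_gr <- tss_window_granges(annotation, window)
  hits <- countOverlaps(w_gr, peaks_granges(peaks$peaks))
  target_set(peaks$dataset_id, peaks$tr_name,
             annotation$symbol[hits > 0], "window",
             list(window = window))
}

#' Nearest-gene target assignment
#'
#' Maps each peak to its nearest-TSS gene, ranks genes by their minimum
#' peak distance, and retains the `n_genes` closest (ties at equal distance
#' broken by symbol). When fewer genes receive any peak, all of them are
#' returned with a warning.
#'
#' @inheritParams assign_targets_window
#' @param n_genes Number of genes to retain.
#' @return A `target_set`.
#' @export
assign_targets_nearest <- function(peaks, annotation, n_genes) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  nt <- nearest_tss(peaks$peaks, annotation)
  nt <- nt[!is.na(nt$gene_symbol), , drop = FALSE]
  if (nrow(nt) == 0)
    return(target_set(peaks$dataset_id, peaks$tr_name, character(),
                      "nearest", list(n_genes = n_genes)))
  dmin <- tapply(nt$distance, nt$gene_symbol, min)
  genes <- names(dmin)
  ord <- order(as.numeric(dmin), genes)
  if (length(genes) < n_genes)
    warning("only ", length(genes), " genes received a peak; returning all")
  keep <- genes[ord][seq_len(min(n_genes, length(genes)))]
  target_set(peaks$dataset_id, peaks$tr_name, keep, "nearest",
             list(n_genes = n_genes))
}

#' Density-based target assignment
#'
#' Scores every gene by aggregating the peaks whose midpoints lie within
#' `range_bp` of its TSS, each weighted by a distance kernel (linear taper
#' `1 - d/range_bp` by default, or exponential `2^(-d/half_life)`), then
#' retains the genes in the top `quantile` of non-zero scores
#' (`ceiling(quantile * #nonzero)` genes; ties at the cutoff broken by
#' symbol).
#'
#' @inheritParams assign_targets_window
#' @param range_bp Aggregation range in bp.
#' @param quantile Retained fraction of non-zero-score genes, in (0, 1).
#' @param kernel `"linear"` or `"exponential"`.
#' @param half_life Half-life (bp) for the exponential kernel.
#' @return A `target_set`; attribute `"scores"` carries the non-zero scores.
#' @export
assign_targets_density <- function(peaks, annotation, range_bp,
                                   quantile = 0.05,
                                   kernel = c("linear", "exponential"),
                                   half_life = range_bp / 10) {
  if (range_bp <= 0) stop("range_bp must be positive")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  kernel <- match.arg(kernel)
  w_gr <- tss_window_granges(annotation, range_bp)
  m_gr <- midpoint_granges(peaks$peaks)
  hits <- findOverlaps(w_gr, m_gr)
  gi <- queryHits(hits)
  pi <- subjectHits(hits)
  d <- abs(peak_midpoint(peaks$peaks)[pi] - annotation$tss[gi])
  keep <- d <= range_bp
  gi <- gi[keep]; d <- d[keep]
  w <- if (kernel == "linear") 1 - d / range_bp else 2^(-d / half_life)
  score <- tapply(w, annotation$symbol[gi], sum)
  score <- score[score > 0]
  n_keep <- ceiling(quantile * length(score))
  ord <- order(-as.numeric(score), names(score))
  genes <- names(score)[ord][seq_len(min(n_keep, length(score)))]
  ts <- target_set(peaks$dataset_id, peaks$tr_name, genes, "density",
                   list(range_bp = range_bp, quantile = quantile,
                        kernel = kernel, half_life = half_life))
  attr(ts, "scores") <- score
  ts
}

#' Build a target-gene library
#'
#' Applies one assignment algorithm to every peak dataset.
#'
#' @param datasets List of [peak_dataset()] objects.
#' @param annotation A [gene_annotation()].
#' @param method `"window"`, `"nearest"` or `"density"`.
#' @param ... Parameters passed to the chosen `assign_targets_*` function.
#' @return A list with class `"target_library"`: `sets` (named by
#'   dataset_id), `meta` (data.frame `dataset_id`, `tr_name`, `n_targets`),
#'   `method`.
#' @export
build_target_library <- function(datasets, annotation,
                                 method = c("window", "nearest", "density"),
                                 ...) {
  method <- match.arg(method)
  fn <- switch(method, window = assign_targets_window,
               nearest = assign_targets_nearest,
               density = assign_targets_density)
  sets <- lapply(datasets, fn, annotation = annotation, ...)
  ids <- vapply(sets, `[[`, "", "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset_id in library")
  names(sets) <- ids
  structure(
    list(sets = sets,
         meta = data.frame(
           dataset_id = ids,
           tr_name = vapply(sets, `[[`, "", "tr_name"),
           n_targets = vapply(sets, function(s) length(s$genes), 0L),
           stringsAsFactors = FALSE, row.names = NULL),
         method = method),
    class = "target_library")
}

#' @export
print.target_library <- function(x, ...) {
  cat("<target_library> ", length(x$sets), " datasets (", x$method,
      "), median targets ", stats::median(x$meta$n_targets), "\n", sep = "")
  invisible(x)
}

#' Write / read a target library TSV (`dataset_id, tr_name, gene`)
#' @param library A `target_library`.
#' @param path File path.
#' @export
write_target_library <- function(library, path) {
  rows <- do.call(rbind, lapply(library$sets, function(s)
    if (length(s$genes))
      data.frame(dataset_id = s$dataset_id, tr_name = s$tr_name,
                 gene = s$genes, stringsAsFactors = FALSE)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_target_library
#' @export
read_target_library <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ids <- unique(df$dataset_id)
  sets <- lapply(ids, function(id) {
    sub <- df[df$dataset_id == id, , drop = FALSE]
    target_set(id, sub$tr_name[1], sub$gene, "file", list(path = path))
  })
  names(sets) <- ids
  structure(
    list(sets = sets,
         meta = data.frame(
           dataset_id = ids,
           tr_name = vapply(sets, `[[`, "", "tr_name"),
           n_targets = vapply(sets, function(s) length(s$genes), 0L),
           stringsAsFactors = FALSE, row.names = NULL),
         method = "file"),
    class = "target_library")
}
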