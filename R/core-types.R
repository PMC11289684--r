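# Domain containers are plain data frames / lists with a class tag and strict
# constructors. Coordinates are 0-based half-open throughout (BED convention);
# conversion to 1-based closed GRanges happens only inside interval helpers.

#' Gene annotation table
#'
#' The mapping backbone for all peak-to-gene logic: one row per gene with its
#' transcription start site (TSS). The TSS is the strand-aware 5' end of the
#' gene, stored as a 0-based position.
#'
#' @param symbol Character vector of gene symbols. Must be unique;
#'   symbols are case-sensitive exact-match tokens (no alias resolution).
#' @param chrom Chromosome name for each gene.
#' @param tss Non-negative integer 0-based TSS position.
#' @param strand `"+"` or `"-"` (recycled if length 1).
#' @return A `data.frame` with class `"gene_annotation"` and columns
#'   `symbol`, `chrom`, `tss`, `strand`.
#' @examples
#' gene_annotation(c("GATA1", "TAL1"), "chr1", c(5000L, 9000L), c("+", "-"))
#' @export
gene_annotation <- function(symbol, chrom, tss, strand = "+") {
  symbol <- as.character(symbol)
  chrom <- as.character(chrom)
  tss <- as.integer(tss)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(symbol))
  if (length(strand) == 1L) strand <- rep(strand, length(symbol))
  strand <- as.character(strand)
  n <- length(symbol)
  if (length(chrom) != n || length(tss) != n || length(strand) != n)
    stop("annotation columns must have equal length")
  if (anyDuplicated(symbol))
    stop("duplicate gene symbol(s): ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  if (n > 0 && (anyNA(tss) || any(tss < 0L)))
    stop("tss positions must be non-negative integers")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  structure(
    data.frame(symbol = symbol, chrom = chrom, tss = tss, strand = strand,
               stringsAsFactors = FALSE),
    class = c("gene_annotation", "data.frame"))
}

# validate/normalise a raw peak table; signal defaults to 1
new_peak_table <- function(chrom, start, end, signal = 1) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  signal <- as.numeric(signal)
  if (length(signal) == 1L) signal <- rep(signal, length(chrom))
  df <- data.frame(chrom = chrom, start = start, end = end, signal = signal,
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (anyNA(df$start) || anyNA(df$end) || any(df$start < 0L))
      stop("peak coordinates must be non-negative integers")
    if (any(df$start >= df$end))
      stop("peak start must be < end (0-based half-open intervals)")
    if (anyNA(df$signal) || any(df$signal < 0))
      stop("peak signal must be non-negative")
  }
  df
}

#' TR ChIP-seq-like peak dataset
#'
#' @param dataset_id Unique dataset identifier.
#' @param tr_name The single TR this dataset profiles (one TR may own many
#'   datasets).
#' @param peaks A data.frame with columns `chrom`, `start`, `end` and
#'   optionally `signal` (read-enrichment strength, default 1), 0-based
#'   half-open.
#' @return A list with class `"peak_dataset"`.
#' @export
peak_dataset <- function(dataset_id, tr_name, peaks) {
  if (is.null(peaks$signal)) peaks$signal <- 1
  structure(
    list(dataset_id = as.character(dataset_id),
         tr_name = as.character(tr_name),
         peaks = new_peak_table(peaks$chrom, peaks$start, peaks$end,
                                peaks$signal)),
    class = "peak_dataset")
}

#' Epigenome signal track
#'
#' A collection of signal peaks from an H3K27ac ChIP-seq or DNase-seq-like
#' assay, serving as a genome-wide activity landscape of cis-regulatory
#' elements.
#'
#' @param sample_id Track identifier.
#' @param assay `"H3K27ac"` or `"DNase"`.
#' @param peaks Peak data.frame as for [peak_dataset()].
#' @return A list with class `"signal_track"`.
#' @export
signal_track <- function(sample_id, assay, peaks) {
  assay <- match.arg(assay, c("H3K27ac", "DNase"))
  if (is.null(peaks$signal)) peaks$signal <- 1
  structure(
    list(sample_id = as.character(sample_id), assay = assay,
         peaks = new_peak_table(peaks$chrom, peaks$start, peaks$end,
                                peaks$signal)),
    class = "signal_track")
}

#' Query gene-set case
#'
#' An ordered list of significant genes (most significant first) together
#' with the known perturbed TR that produced it, emulating a differential
#' expression gene set from a TR knockdown experiment.
#'
#' @param case_id Case identifier.
#' @param genes Character vector of unique gene symbols, significance order.
#' @param true_tr The planted/perturbed TR label (ground truth).
#' @param G Input-size parameter; defaults to `length(genes)`.
#' @return A list with class `"query_case"`.
#' @export
query_case <- function(case_id, genes, true_tr, G = length(genes)) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene(s) in query case '", case_id, "'")
  G <- as.integer(G)
  if (G < 1L) stop("G must be a positive integer")
  if (length(genes) < G)
    stop("case '", case_id, "' has fewer genes than G = ", G)
  structure(
    list(case_id = as.character(case_id), genes = genes,
         true_tr = as.character(true_tr), G = G),
    class = "query_case")
}

#' Truncate a query case to its top G genes
#'
#' @param case A [query_case()].
#' @param G Number of most-significant genes to keep.
#' @return A new `query_case` with the top `G` genes.
#' @export
truncate_case <- function(case, G) {
  G <- as.integer(G)
  if (length(case$genes) < G)
    stop("case '", case$case_id, "' has only ", length(case$genes),
         " genes; cannot truncate to G = ", G)
  query_case(case$case_id, case$genes[seq_len(G)], case$true_tr, G)
}

#' 2x2 contingency table for gene-set enrichment
#'
#' Cells partition the background universe: `a` = query AND target, `b` =
#' query not target, `c` = (background minus query) AND target, `d` =
#' remainder.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A list with class `"contingency_table"`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != floor(cells)))
    stop("contingency cells must be non-negative integers")
  structure(as.list(setNames(as.integer(cells), names(cells))),
            class = "contingency_table")
}

#' Construct a ranking list
#'
#' The universal output of every ranker: TR (or TR-dataset) terms ordered by
#' the stated sort key, with ranks 1..L and no gaps.
#'
#' @param terms A data.frame with columns `tr_name` and optionally
#'   `dataset_id`, `score`, `p`, `q`; one row per ranked term, already in
#'   rank order (row 1 = rank 1).
#' @return A `data.frame` with class `"ranking_list"` and columns `rank`,
#'   `tr_name`, `dataset_id`, `score`, `p`, `q`.
#' @export
ranking_list <- function(terms) {
  n <- nrow(terms)
  out <- data.frame(
    rank = seq_len(n),
    tr_name = as.character(terms$tr_name),
    dataset_id = if (is.null(terms$dataset_id)) NA_character_ else
      as.character(terms$dataset_id),
    score = if (is.null(terms$score)) NA_real_ else as.numeric(terms$score),
    p = if (is.null(terms$p)) NA_real_ else as.numeric(terms$p),
    q = if (is.null(terms$q)) NA_real_ else as.numeric(terms$q),
    stringsAsFactors = FALSE)
  for (col in c("p", "q")) {
    v <- out[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " values must lie in [0, 1]")
  }
  structure(out, class = c("ranking_list", "data.frame"))
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("<gene_annotation> ", nrow(x), " genes on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  if (nrow(x)) print.data.frame(head(x, 6))
  invisible(x)
}

#' @export
print.peak_dataset <- function(x, ...) {
  cat("<peak_dataset> ", x$dataset_id, " (TR ", x$tr_name, "): ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> ", x$sample_id, " [", x$assay, "]: ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' @export
print.query_case <- function(x, ...) {
  cat("<query_case> ", x$case_id, ": ", length(x$genes),
      " genes, perturbed TR ", x$true_tr, " (G = ", x$G, ")\n", sep = "")
  invisible(x)
}
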