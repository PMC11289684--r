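# Interval helpers. Internally 0-based half-open [start, end) tables are
# converted to 1-based closed GRanges: [start, end) -> start+1 .. end, so a
# peak [100,200) does NOT overlap a window [200,300).

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

# 0-based peak midpoint, floor((start+end)/2)
peak_midpoint <- function(peaks) {
  as.integer(floor((as.numeric(peaks$start) + as.numeric(peaks$end)) / 2))
}

midpoint_granges <- function(peaks) {
  mid <- peak_midpoint(peaks)
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = mid + 1L, width = 1L))
}

# symmetric TSS windows: 0-based [tss - window, tss + window)
tss_window_granges <- function(annotation, window) {
  start0 <- pmax(annotation$tss - window, 0L)
  GenomicRanges::GRanges(annotation$chrom,
                         IRanges::IRanges(start = start0 + 1L,
                                          end = annotation$tss + window))
}

# strand-aware promoter windows: upstream in the direction of transcription
promoter_granges <- function(annotation, upstream, downstream) {
  plus <- annotation$strand == "+"
  start0 <- ifelse(plus, annotation$tss - upstream, annotation$tss - downstream)
  end0 <- ifelse(plus, annotation$tss + downstream, annotation$tss + upstream)
  start0 <- pmax(start0, 0L)
  GenomicRanges::GRanges(annotation$chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0))
}

#' Nearest TSS for each peak
#'
#' Maps each peak (by its midpoint, `floor((start+end)/2)`) to the annotated
#' gene minimizing the linear distance `|midpoint - tss|`. Ties are broken
#' deterministically by the lexicographically smallest symbol. Peaks on
#' chromosomes absent from the annotation are skipped with a warning and
#' return `NA`.
#'
#' @param peaks Peak data.frame (`chrom`, `start`, `end`, ...).
#' @param annotation A [gene_annotation()].
#' @return A data.frame with one row per peak: `gene_symbol`, `distance`.
#' @export
nearest_tss <- function(peaks, annotation) {
  if (nrow(annotation) == 0) stop("annotation is empty")
  n <- nrow(peaks)
  gene <- rep(NA_character_, n)
  dist <- rep(NA_integer_, n)
  mid <- peak_midpoint(peaks)
  for (chr in unique(peaks$chrom)) {
    pk <- which(peaks$chrom == chr)
    ann <- annotation[annotation$chrom == chr, , drop = FALSE]
    if (nrow(ann) == 0) next
    # collapse duplicate TSS positions to their lexicographically smallest
    # symbol: under the tie rule no other co-located gene can win
    ord <- order(ann$tss, ann$symbol)
    tss <- ann$tss[ord]
    sym <- ann$symbol[ord]
    keep <- !duplicated(tss)
    tss <- tss[keep]
    sym <- sym[keep]
    m <- mid[pk]
    i <- findInterval(m, tss)
    left_t <- ifelse(i >= 1L, tss[pmax(i, 1L)], NA_integer_)
    right_t <- ifelse(i < length(tss), tss[pmin(i + 1L, length(tss))],
                      NA_integer_)
    dl <- ifelse(is.na(left_t), Inf, m - left_t)
    dr <- ifelse(is.na(right_t), Inf, right_t - m)
    ls <- ifelse(i >= 1L, sym[pmax(i, 1L)], NA_character_)
    rs <- ifelse(i < length(tss), sym[pmin(i + 1L, length(tss))],
                 NA_character_)
    pick_left <- dl < dr | (dl == dr & (is.na(rs) | (!is.na(ls) & ls <= rs)))
    gene[pk] <- ifelse(pick_left, ls, rs)
    dist[pk] <- as.integer(pmin(dl, dr))
  }
  skipped <- is.na(gene)
  if (any(skipped))
    warning(sum(skipped), " peak(s) on chromosome(s) absent from the ",
            "annotation were skipped")
  data.frame(gene_symbol = gene, distance = dist, stringsAsFactors = FALSE)
}

#' Nearest TSS for a single peak
#'
#' Scalar convenience around [nearest_tss()].
#'
#' @param peak A one-row peak data.frame or list with `chrom`, `start`, `end`.
#' @param annotation A [gene_annotation()].
#' @return A list with `gene_symbol` and `distance`, or `NULL` (with a
#'   warning) when the peak's chromosome is absent from the annotation.
#' @export
nearest_tss_distance <- function(peak, annotation) {
  df <- data.frame(chrom = peak$chrom[1], start = peak$start[1],
                   end = peak$end[1], stringsAsFactors = FALSE)
  res <- nearest_tss(df, annotation)
  if (is.na(res$gene_symbol[1])) return(NULL)
  list(gene_symbol = res$gene_symbol[1], distance = res$distance[1])
}
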