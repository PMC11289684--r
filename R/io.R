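# Readers/writers for the plain-text carriers: TSV (annotation, rankings),
# BED (peaks, tracks), GMT (query gene sets). All round-trips are lossless
# for the fields used downstream.

#' Read a gene annotation TSV
#'
#' Expects a header line `symbol  chrom  tss  strand` followed by one row per
#' gene. An empty file yields an empty annotation with a warning.
#'
#' @param path File path.
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) <= 1L) {
    warning("annotation file '", path, "' is empty")
    return(gene_annotation(character(), character(), integer(), character()))
  }
  body <- lines[-1L]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed annotation row at line ",
         which(nf != 4L)[1] + 1L, " of ", path)
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  tss <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(tss))
    stop("non-integer tss at line ", which(is.na(tss))[1] + 1L, " of ", path)
  gene_annotation(m[, 1], m[, 2], tss, m[, 4])
}

#' Write a gene annotation TSV
#' @param annotation A [gene_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(annotation, path) {
  write.table(as.data.frame(annotation), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BED file of peaks
#'
#' Column 5 (BED score) is read as the peak signal when present; otherwise
#' every peak gets signal 1. Intervals are kept 0-based half-open exactly as
#' stored.
#'
#' @param path BED file path.
#' @param dataset_id,tr_name Identifiers for the resulting dataset.
#' @return A [peak_dataset()].
#' @export
read_peaks <- function(path, dataset_id, tr_name) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(peak_dataset(dataset_id, tr_name,
                        data.frame(chrom = character(), start = integer(),
                                   end = integer(), signal = numeric())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED row at line ", which(nf < 3L)[1], " of ", path)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end))
    stop("non-integer coordinate at line ",
         which(is.na(start) | is.na(end))[1], " of ", path)
  signal <- ifelse(nf >= 5L,
                   suppressWarnings(as.numeric(
                     vapply(fields, function(f) if (length(f) >= 5L) f[[5L]]
                            else "1", ""))),
                   1)
  peak_dataset(dataset_id, tr_name,
               data.frame(chrom = chrom, start = start, end = end,
                          signal = signal, stringsAsFactors = FALSE))
}

#' Write peaks as BED
#'
#' Writes `chrom start end name score` with the signal in the score column.
#'
#' @param x A [peak_dataset()], [signal_track()] or raw peak data.frame.
#' @param path Output path.
#' @export
write_peaks <- function(x, path) {
  peaks <- if (is.data.frame(x)) x else x$peaks
  id <- if (is.data.frame(x)) "peak" else
    if (inherits(x, "signal_track")) x$sample_id else x$dataset_id
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end,
                    paste0(id, "_", seq_len(nrow(peaks))), peaks$signal)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read query cases from a GMT file
#'
#' GMT dialect: `case_id <TAB> true_tr <TAB> gene1 <TAB> gene2 ...` with
#' genes in significance order (most significant first). The description
#' field carries the perturbed-TR label.
#'
#' @param path GMT file path.
#' @return A list of [query_case()] objects.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1], " of ", path,
         " has fewer than 3 fields")
  lapply(fields, function(f)
    query_case(f[[1L]], f[-c(1L, 2L)], f[[2L]]))
}

#' Write query cases as GMT
#' @param cases List of [query_case()] objects.
#' @param path Output path.
#' @export
write_gene_sets <- function(cases, path) {
  lines <- vapply(cases, function(cs)
    paste(c(cs$case_id, cs$true_tr, cs$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a ranking list TSV
#'
#' Columns: `rank, tr_name, dataset_id, score, p, q`.
#'
#' @param path File path.
#' @return A [ranking_list()].
#' @export
read_ranking <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df <- df[order(df$rank), , drop = FALSE]
  ranking_list(df)
}

#' @rdname read_ranking
#' @param ranking A [ranking_list()].
#' @export
write_ranking <- function(ranking, path) {
  write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
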