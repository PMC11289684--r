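# findInterval-based fast paths for the per-dataset inner loops of the
# region/RP rankers. Semantics are identical to the GRanges route (0-based
# half-open intervals); tests cross-check the two. GRanges remains the
# general-purpose machinery elsewhere.

# per-chromosome TSS index: sorted TSS positions with their gene row indices
tss_index <- function(annotation) {
  lapply(split(seq_len(nrow(annotation)), annotation$chrom), function(ix) {
    o <- order(annotation$tss[ix])
    list(tss = annotation$tss[ix][o], gene = ix[o])
  })
}

# (peak row, gene row, distance) pairs for all peaks whose midpoint lies
# within `window` of a TSS
midpoint_gene_pairs <- function(peaks, tidx, window) {
  mid <- peak_midpoint(peaks)
  out_peak <- integer(0); out_gene <- integer(0); out_d <- integer(0)
  for (chr in intersect(unique(peaks$chrom), names(tidx))) {
    sel <- which(peaks$chrom == chr)
    ti <- tidx[[chr]]
    m <- mid[sel]
    lo <- findInterval(m - window - 1L, ti$tss) + 1L
    hi <- findInterval(m + window, ti$tss)
    n <- hi - lo + 1L
    keep <- n > 0L
    if (!any(keep)) next
    gpos <- sequence(n[keep], from = lo[keep])
    prep <- rep(sel[keep], n[keep])
    out_peak <- c(out_peak, prep)
    out_gene <- c(out_gene, ti$gene[gpos])
    out_d <- c(out_d, abs(ti$tss[gpos] - mid[prep]))
  }
  list(peak = out_peak, gene = out_gene, dist = out_d)
}

# RP vector via the midpoint index; same result as compute_rp()
fast_rp <- function(peaks, tidx, n_genes, window, decay, half_life) {
  rp <- numeric(n_genes)
  pr <- midpoint_gene_pairs(peaks, tidx, window)
  if (length(pr$peak)) {
    w <- if (decay == "uniform") rep(1, length(pr$dist)) else
      2^(-pr$dist / half_life)
    agg <- rowsum(peaks$signal[pr$peak] * w, pr$gene)
    rp[as.integer(rownames(agg))] <- agg[, 1]
  }
  rp
}

# per-gene max signal over peaks whose INTERVAL overlaps [tss-w, tss+w);
# a window overlaps peak [s,e) iff tss lies in [s-w+1, e+w-1]
fast_max_signal <- function(peaks, tidx, n_genes, window) {
  prof <- numeric(n_genes)
  for (chr in intersect(unique(peaks$chrom), names(tidx))) {
    sel <- which(peaks$chrom == chr)
    ti <- tidx[[chr]]
    lo <- findInterval(peaks$start[sel] - window, ti$tss) + 1L
    hi <- findInterval(peaks$end[sel] + window - 1L, ti$tss)
    n <- hi - lo + 1L
    keep <- n > 0L
    if (!any(keep)) next
    gpos <- ti$gene[sequence(n[keep], from = lo[keep])]
    sig <- rep(peaks$signal[sel[keep]], n[keep])
    mx <- tapply(sig, gpos, max)
    gi <- as.integer(names(mx))
    prof[gi] <- pmax(prof[gi], as.numeric(mx))
  }
  prof
}

# per-chromosome disjoint-interval index from a reduced GRanges
merged_interval_index <- function(gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s <- GenomicRanges::start(gr) - 1L   # back to 0-based half-open
  e <- GenomicRanges::end(gr)
  lapply(split(seq_along(chrom), chrom), function(ix) {
    o <- order(s[ix])
    list(start = s[ix][o], end = e[ix][o])
  })
}

# indices of peaks overlapping any interval of a merged (disjoint, sorted)
# index; [s,e) vs [S,E) overlap iff s < E and e > S
overlapping_peaks <- function(peaks, midx) {
  hit <- logical(nrow(peaks))
  for (chr in intersect(unique(peaks$chrom), names(midx))) {
    sel <- which(peaks$chrom == chr)
    mi <- midx[[chr]]
    i <- findInterval(peaks$end[sel] - 1L, mi$start)
    ok <- i >= 1L
    ok[ok] <- mi$end[i[ok]] > peaks$start[sel][ok]
    hit[sel] <- ok
  }
  which(hit)
}
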