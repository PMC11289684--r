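# Synthetic regulatory universe with planted ground-truth regulators.
# Emulates the statistical structure the benchmark assumes: TR ChIP-seq-like
# peak datasets concentrated near the TSSs of each TR's true target genes,
# skewed per-TR dataset multiplicity (a few deeply profiled TRs, many with a
# single dataset), epigenome signal tracks marking regulated genes, and
# query gene sets mixing true targets with noise genes.

#' Generator configuration
#'
#' Defaults define the study conditions used throughout the package's tests
#' and examples: 5,000 genes on 5 chromosomes of 20 Mb; 50 TRs of which 40%
#' are deeply profiled (10 datasets each, the rest 1); popularity-weighted
#' (overlapping) target sets of 150-250 genes; 200-bp peaks whose midpoints
#' fall near a target TSS with probability 0.9 (Normal displacement, per-TR
#' SD on a log-spaced 0.3-5 kb spectrum) and otherwise uniformly within
#' +/-100 kb; 60 nonspecific HOT-region peaks and 300 uniform background
#' peaks per dataset; log-normal signals with a x3 boost for true-target
#' peaks; and a query noise fraction that increases with the input size G
#' (0.65 / 0.80 / 0.90 at G = 200 / 600 / 1000), with noise genes drawn by
#' popularity to emulate indirect knockdown effects.
#'
#' @param n_genes,n_chroms,chrom_length Gene universe geometry.
#' @param n_trs Number of transcriptional regulators.
#' @param targets_per_tr Length-2 integer range; each TR draws its target
#'   count uniformly from this range.
#' @param target_popularity_sdlog SD (log scale) of the log-normal
#'   gene-popularity weights used when TRs sample their targets; 0 gives
#'   independent uniform target sets, larger values concentrate regulation
#'   on hub genes shared across TRs (high-occupancy target regions), making
#'   TR target sets overlap as they do in real compendia.
#' @param multi_fraction Fraction of TRs profiled by `multi_datasets`
#'   datasets; all remaining TRs get exactly one dataset.
#' @param multi_datasets Dataset count for the deeply profiled TRs.
#' @param peak_width Width (bp) of every simulated peak.
#' @param proximal_fraction Probability that a true-target peak is proximal
#'   (Normal displacement) rather than distal (uniform displacement).
#' @param proximal_sd SD (bp) of the Normal peak-to-TSS displacement.
#'   A length-2 range gives every TR its own SD, drawn log-uniformly from
#'   the range: real factors differ widely in how promoter-proximal their
#'   binding is, and this heterogeneity is what makes the choice of a TSS
#'   window cutoff re-order TRs.
#' @param distal_range Half-width (bp) of the uniform distal displacement.
#' @param background_peaks Uniform background peaks per dataset.
#' @param hot_peaks Nonspecific peaks per dataset placed near the TSSs of
#'   popularity-sampled hub genes, emulating high-occupancy-target (HOT)
#'   regions that attract ChIP signal for almost every factor.
#' @param signal_meanlog,signal_sdlog Log-normal peak-signal parameters.
#' @param target_signal_boost Multiplicative signal boost for true-target
#'   peaks.
#' @param noise_fraction Named numeric vector mapping query size G to the
#'   fraction of noise (non-target) genes; interpolated linearly in G and
#'   must be non-decreasing.
#' @param n_tracks,informative_tracks Signal-track counts (total and
#'   informative).
#' @param track_tr_coverage Fraction of TR programs each informative track
#'   covers. Tracks emulate epigenomes of different cell types, each with
#'   its own active subset of regulatory programs; this heterogeneity is
#'   what lets stepwise selection find tracks matched to a query.
#' @param track_background_peaks Background peaks per track.
#' @param track_peak_width Width (bp) of track peaks.
#' @param track_proximal_sd SD (bp) of informative track peak placement
#'   around regulated-gene TSSs.
#' @param track_signal_boost Multiplicative signal boost for informative
#'   track peaks at regulated genes.
#' @return A list with class `"generator_config"`.
#' @export
generator_config <- function(n_genes = 5000L,
                             n_chroms = 5L,
                             chrom_length = 2e7,
                             n_trs = 50L,
                             targets_per_tr = c(150L, 250L),
                             target_popularity_sdlog = 2,
                             multi_fraction = 0.4,
                             multi_datasets = 10L,
                             peak_width = 200L,
                             proximal_fraction = 0.9,
                             proximal_sd = c(300, 5000),
                             distal_range = 1e5,
                             background_peaks = 300L,
                             hot_peaks = 60L,
                             signal_meanlog = 0,
                             signal_sdlog = 0.5,
                             target_signal_boost = 3,
                             noise_fraction = c("200" = 0.65, "600" = 0.8,
                                                "1000" = 0.9),
                             n_tracks = 10L,
                             informative_tracks = 6L,
                             track_tr_coverage = 0.5,
                             track_background_peaks = 2000L,
                             track_peak_width = 500L,
                             track_proximal_sd = 1000,
                             track_signal_boost = 3) {
  cfg <- list(n_genes = as.integer(n_genes), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_trs = as.integer(n_trs),
              targets_per_tr = as.integer(targets_per_tr),
              target_popularity_sdlog = target_popularity_sdlog,
              multi_fraction = multi_fraction,
              multi_datasets = as.integer(multi_datasets),
              peak_width = as.integer(peak_width),
              proximal_fraction = proximal_fraction,
              proximal_sd = proximal_sd, distal_range = distal_range,
              background_peaks = as.integer(background_peaks),
              hot_peaks = as.integer(hot_peaks),
              signal_meanlog = signal_meanlog, signal_sdlog = signal_sdlog,
              target_signal_boost = target_signal_boost,
              noise_fraction = noise_fraction,
              n_tracks = as.integer(n_tracks),
              informative_tracks = as.integer(informative_tracks),
              track_tr_coverage = track_tr_coverage,
              track_background_peaks = as.integer(track_background_peaks),
              track_peak_width = as.integer(track_peak_width),
              track_proximal_sd = track_proximal_sd,
              track_signal_boost = track_signal_boost)
  probs <- c(cfg$proximal_fraction, cfg$multi_fraction)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(cfg$noise_fraction < 0 | cfg$noise_fraction > 1))
    stop("noise_fraction values must lie in [0, 1]")
  if (is.unsorted(cfg$noise_fraction[order(as.numeric(names(cfg$noise_fraction)))]))
    stop("noise_fraction must be non-decreasing in G")
  if (cfg$peak_width <= 0 || cfg$track_peak_width <= 0)
    stop("peak widths must be positive")
  if (length(cfg$targets_per_tr) != 2L ||
      cfg$targets_per_tr[1] > cfg$targets_per_tr[2])
    stop("targets_per_tr must be an ordered length-2 range")
  if (max(cfg$targets_per_tr) > cfg$n_genes)
    stop("targets_per_tr exceeds the number of genes")
  structure(cfg, class = "generator_config")
}

# noise fraction for an arbitrary G by linear interpolation (constant
# extrapolation at the ends)
noise_fraction_at <- function(config, G) {
  g <- as.numeric(names(config$noise_fraction))
  v <- as.numeric(config$noise_fraction)
  if (length(g) == 1L) return(v)
  stats::approx(g, v, xout = G, rule = 2)$y
}

#' Simulate the synthetic universe
#'
#' Places TSSs on a jittered grid (no collisions), assigns each TR a target
#' gene set drawn uniformly without replacement, and fixes the skewed
#' dataset-multiplicity map. Deterministic given `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A list with class `"synthetic_universe"`: `annotation`, `trs`
#'   (data.frame `tr_name`, `n_datasets`), `targets` (named list of target
#'   gene sets), `config`, `seed`.
#' @export
simulate_universe <- function(config = generator_config(), seed = 1L) {
  set.seed(seed)
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  spacing <- floor(config$chrom_length / (per_chrom + 1))
  if (spacing < 10L)
    stop("chrom_length too small for the requested gene count")
  ann <- do.call(rbind, lapply(seq_len(config$n_chroms), function(ci) {
    n_here <- min(per_chrom, config$n_genes - (ci - 1L) * per_chrom)
    if (n_here <= 0L) return(NULL)
    anchor <- spacing * seq_len(n_here)
    jitter <- floor(runif(n_here, -0.4, 0.4) * spacing)
    data.frame(chrom = paste0("chr", ci), tss = as.integer(anchor + jitter),
               strand = sample(c("+", "-"), n_here, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  width <- max(nchar(as.character(config$n_genes)), 4L)
  symbol <- sprintf(paste0("G%0", width, "d"), seq_len(nrow(ann)))
  annotation <- gene_annotation(symbol, ann$chrom, ann$tss, ann$strand)

  tr_name <- sprintf("TR%03d", seq_len(config$n_trs))
  n_multi <- round(config$multi_fraction * config$n_trs)
  n_datasets <- c(rep(config$multi_datasets, n_multi),
                  rep(1L, config$n_trs - n_multi))
  tgt_range <- seq(config$targets_per_tr[1], config$targets_per_tr[2])
  n_targets <- tgt_range[sample.int(length(tgt_range), config$n_trs,
                                    replace = TRUE)]
  # fixed log-spaced spectrum of binding-distance scales: every universe
  # spans the same proximal-to-distal mix of factors. The deeply profiled
  # TRs take the distal (enhancer-biased) end of the spectrum - mirroring
  # the broadly acting, heavily studied master regulators - shuffled within
  # each multiplicity group.
  sd_rng <- range(config$proximal_sd)
  spectrum <- if (sd_rng[1] <= 0 || sd_rng[1] == sd_rng[2])
    seq(sd_rng[1], sd_rng[2], length.out = config$n_trs)
  else
    exp(seq(log(sd_rng[1]), log(sd_rng[2]), length.out = config$n_trs))
  tr_proximal_sd <- if (n_multi %in% c(0L, config$n_trs)) {
    sample(spectrum)
  } else {
    c(sample(spectrum[seq(config$n_trs - n_multi + 1, config$n_trs)]),
      sample(spectrum[seq_len(config$n_trs - n_multi)]))
  }
  popularity <- setNames(rlnorm(length(symbol), 0,
                                config$target_popularity_sdlog), symbol)
  targets <- lapply(n_targets, function(k)
    sort(sample(symbol, k, prob = popularity)))
  names(targets) <- tr_name

  structure(
    list(annotation = annotation,
         trs = data.frame(tr_name = tr_name, n_datasets = n_datasets,
                          n_targets = n_targets,
                          proximal_sd = tr_proximal_sd,
                          stringsAsFactors = FALSE),
         targets = targets, popularity = popularity, config = config,
         seed = as.integer(seed)),
    class = "synthetic_universe")
}

#' @export
print.synthetic_universe <- function(x, ...) {
  cat("<synthetic_universe> ", nrow(x$annotation), " genes, ",
      nrow(x$trs), " TRs, ", sum(x$trs$n_datasets),
      " datasets (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# clip a vector of 0-based midpoints into [half_width, L - half_width]
clip_mid <- function(mid, half_width, chrom_length) {
  pmin(pmax(mid, half_width), floor(chrom_length) - half_width - 1)
}

#' Simulate TR ChIP-seq-like peak datasets
#'
#' For each dataset of TR t: one peak per target gene, displaced from the
#' target TSS by Normal(0, `proximal_sd`) with probability
#' `proximal_fraction` and otherwise uniformly within `+/- distal_range`,
#' plus `background_peaks` uniform peaks. Signals are log-normal; true-target
#' peaks are boosted by `target_signal_boost`.
#'
#' @param universe A [simulate_universe()] result.
#' @param seed Integer seed.
#' @return List of [peak_dataset()] objects (dataset ids `TRxxx_dY`).
#' @export
simulate_peak_datasets <- function(universe, seed = 1L) {
  set.seed(seed)
  cfg <- universe$config
  ann <- universe$annotation
  half <- cfg$peak_width %/% 2L
  chroms <- unique(ann$chrom)
  out <- list()
  for (i in seq_len(nrow(universe$trs))) {
    tr <- universe$trs$tr_name[i]
    tgt <- universe$targets[[tr]]
    tr_sd <- universe$trs$proximal_sd[i]
    idx <- match(tgt, ann$symbol)
    for (d in seq_len(universe$trs$n_datasets[i])) {
      n_t <- length(tgt)
      proximal <- runif(n_t) < cfg$proximal_fraction
      disp <- ifelse(proximal,
                     round(rnorm(n_t, 0, tr_sd)),
                     round(runif(n_t, -cfg$distal_range, cfg$distal_range)))
      mid <- clip_mid(ann$tss[idx] + disp, half, cfg$chrom_length)
      sig_t <- rlnorm(n_t, cfg$signal_meanlog, cfg$signal_sdlog) *
        cfg$target_signal_boost
      n_h <- min(cfg$hot_peaks, nrow(ann))
      hot_idx <- if (n_h > 0)
        sample.int(nrow(ann), n_h, prob = universe$popularity) else integer(0)
      hot_mid <- clip_mid(ann$tss[hot_idx] +
                            round(rnorm(n_h, 0, tr_sd)),
                          half, cfg$chrom_length)
      sig_h <- rlnorm(n_h, cfg$signal_meanlog, cfg$signal_sdlog)
      n_b <- cfg$background_peaks
      bg_chrom <- sample(chroms, n_b, replace = TRUE)
      bg_mid <- clip_mid(floor(runif(n_b, 0, cfg$chrom_length)), half,
                         cfg$chrom_length)
      sig_b <- rlnorm(n_b, cfg$signal_meanlog, cfg$signal_sdlog)
      peaks <- data.frame(
        chrom = c(ann$chrom[idx], ann$chrom[hot_idx], bg_chrom),
        start = as.integer(c(mid, hot_mid, bg_mid) - half),
        end = as.integer(c(mid, hot_mid, bg_mid) - half + cfg$peak_width),
        signal = c(sig_t, sig_h, sig_b), stringsAsFactors = FALSE)
      id <- sprintf("%s_d%d", tr, d)
      out[[id]] <- peak_dataset(id, tr, peaks)
    }
  }
  out
}

#' Simulate epigenome signal tracks
#'
#' `informative` tracks emulate the epigenome of a cell type in which a
#' random subset of the TR programs (`track_tr_coverage` of them) is
#' active: boosted-signal peaks are placed near the TSSs of the covered
#' TRs' target genes. The remaining tracks contain only uniform background
#' peaks. Assays alternate H3K27ac / DNase round-robin, so both assays span
#' informative and noise tracks.
#'
#' @param universe A [simulate_universe()] result.
#' @param n_tracks Number of tracks (default from the config).
#' @param seed Integer seed.
#' @param n_informative Number of informative tracks (default from config).
#' @return List of [signal_track()] objects; attribute `"informative"` holds
#'   the informative sample ids.
#' @export
simulate_signal_tracks <- function(universe,
                                   n_tracks = universe$config$n_tracks,
                                   seed = 1L,
                                   n_informative =
                                     universe$config$informative_tracks) {
  if (n_tracks < 1L) stop("n_tracks must be >= 1")
  set.seed(seed)
  cfg <- universe$config
  ann <- universe$annotation
  half <- cfg$track_peak_width %/% 2L
  chroms <- unique(ann$chrom)
  n_informative <- min(n_informative, n_tracks)
  n_cov <- max(1L, round(cfg$track_tr_coverage * nrow(universe$trs)))
  out <- vector("list", n_tracks)
  ids <- sprintf("track%02d", seq_len(n_tracks))
  covered <- vector("list", n_tracks)
  names(covered) <- ids
  for (j in seq_len(n_tracks)) {
    informative <- j <= n_informative
    if (informative) {
      covered[[j]] <- sort(sample(universe$trs$tr_name, n_cov))
      regulated <- sort(unique(unlist(universe$targets[covered[[j]]])))
      idx <- match(regulated, ann$symbol)
    }
    n_b <- cfg$track_background_peaks
    bg_mid <- clip_mid(floor(runif(n_b, 0, cfg$chrom_length)), half,
                       cfg$chrom_length)
    peaks <- data.frame(
      chrom = sample(chroms, n_b, replace = TRUE),
      mid = bg_mid,
      signal = rlnorm(n_b, cfg$signal_meanlog, cfg$signal_sdlog),
      stringsAsFactors = FALSE)
    if (informative) {
      disp <- round(rnorm(length(idx), 0, cfg$track_proximal_sd))
      mid <- clip_mid(ann$tss[idx] + disp, half, cfg$chrom_length)
      peaks <- rbind(data.frame(
        chrom = ann$chrom[idx], mid = mid,
        signal = rlnorm(length(idx), cfg$signal_meanlog, cfg$signal_sdlog) *
          cfg$track_signal_boost,
        stringsAsFactors = FALSE), peaks)
    }
    assay <- if (j %% 2L == 1L) "H3K27ac" else "DNase"
    out[[j]] <- signal_track(ids[j], assay, data.frame(
      chrom = peaks$chrom,
      start = as.integer(peaks$mid - half),
      end = as.integer(peaks$mid - half + cfg$track_peak_width),
      signal = peaks$signal, stringsAsFactors = FALSE))
  }
  names(out) <- ids
  attr(out, "informative") <- ids[seq_len(n_informative)]
  attr(out, "covered_trs") <- covered[seq_len(n_informative)]
  out
}

#' Simulate query gene-set cases
#'
#' Each case picks a TR uniformly at random; its gene list is a shuffled
#' subset of the TR's true targets (significance-ordered first) padded with
#' shuffled noise genes so that the fraction of noise genes equals
#' `noise_fraction(G)` (capped by the TR's target count, so larger G can
#' only increase the realized noise fraction). Noise genes are drawn with
#' the universe's gene-popularity weights, emulating indirect perturbation
#' effects that cascade preferentially through highly regulated hub genes.
#'
#' @param universe A [simulate_universe()] result.
#' @param G Query size (number of genes per case).
#' @param n_cases Number of cases.
#' @param seed Integer seed.
#' @return List of [query_case()] objects.
#' @export
simulate_query_cases <- function(universe, G = 200L, n_cases = 100L,
                                 seed = 1L) {
  if (G > nrow(universe$annotation))
    stop("G exceeds the gene universe size")
  set.seed(seed)
  cfg <- universe$config
  symbols <- universe$annotation$symbol
  nf <- noise_fraction_at(cfg, G)
  trs <- sample(universe$trs$tr_name, n_cases, replace = TRUE)
  lapply(seq_len(n_cases), function(i) {
    tr <- trs[i]
    tgt <- universe$targets[[tr]]
    n_true <- min(round((1 - nf) * G), length(tgt), G)
    true_genes <- sample(tgt, n_true)
    noise_pool <- setdiff(symbols, tgt)
    noise_genes <- sample(noise_pool, G - n_true,
                          prob = universe$popularity[noise_pool])
    query_case(sprintf("case%03d_G%d", i, G),
               c(true_genes, noise_genes), tr, G)
  })
}

#' Simulate a full benchmark scenario
#'
#' Convenience wrapper producing universe, datasets, tracks and cases from a
#' single root seed via named substreams.
#'
#' @param config A [generator_config()].
#' @param seed Root integer seed.
#' @param G Query sizes (vector); one case list per value.
#' @param n_cases Cases per G.
#' @return A list `universe`, `datasets`, `tracks`, `cases` (named list by
#'   G), `seed`.
#' @export
simulate_benchmark <- function(config = generator_config(), seed = 1L,
                               G = 200L, n_cases = 100L) {
  universe <- simulate_universe(config, substream_seed(seed, "universe"))
  datasets <- simulate_peak_datasets(universe, substream_seed(seed, "peaks"))
  tracks <- simulate_signal_tracks(universe,
                                   seed = substream_seed(seed, "tracks"))
  cases <- lapply(G, function(g)
    simulate_query_cases(universe, g, n_cases,
                         substream_seed(seed, paste0("cases", g))))
  names(cases) <- as.character(G)
  list(universe = universe, datasets = datasets, tracks = tracks,
       cases = cases, seed = as.integer(seed))
}
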