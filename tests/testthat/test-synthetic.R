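# Generator determinism, planted structure, and degenerate-parameter
# behaviour.

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config()
  u1 <- simulate_universe(cfg, seed = 5)
  u2 <- simulate_universe(cfg, seed = 5)
  expect_identical(u1, u2)
  d1 <- simulate_peak_datasets(u1, seed = 6)
  d2 <- simulate_peak_datasets(u2, seed = 6)
  expect_identical(d1, d2)
  t1 <- simulate_signal_tracks(u1, seed = 7)
  t2 <- simulate_signal_tracks(u1, seed = 7)
  expect_identical(t1, t2)
  c1 <- simulate_query_cases(u1, G = 50, n_cases = 4, seed = 8)
  c2 <- simulate_query_cases(u1, G = 50, n_cases = 4, seed = 8)
  expect_identical(c1, c2)
  u3 <- simulate_universe(cfg, seed = 99)
  expect_false(identical(u1$targets, u3$targets))
})

test_that("dataset multiplicity follows the configured skew exactly", {
  cfg <- generator_config(n_genes = 300L, n_chroms = 1L, chrom_length = 3e6,
                          n_trs = 50L, targets_per_tr = c(20L, 30L),
                          multi_fraction = 0.4, multi_datasets = 10L)
  uni <- simulate_universe(cfg, seed = 2)
  expect_equal(sum(uni$trs$n_datasets), 20 * 10 + 30 * 1)   # 230
  expect_equal(as.vector(table(uni$trs$n_datasets)), c(30, 20))
  ds <- simulate_peak_datasets(uni, seed = 3)
  expect_length(ds, 230)
  got <- table(vapply(ds, `[[`, "", "tr_name"))
  expect_equal(sort(unique(as.vector(got))), c(1, 10))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(targets_per_tr = c(50L, 700L), n_genes = 600L),
               "exceeds")
  expect_error(generator_config(proximal_fraction = 1.4), "probabilities")
  expect_error(generator_config(noise_fraction = c("200" = 0.5, "600" = 0.3)),
               "non-decreasing")
  expect_error(simulate_universe(generator_config(n_genes = 5000L,
                                                  chrom_length = 5e3),
                                 seed = 1),
               "too small")
})

test_that("degenerate peak parameters place peaks exactly on target TSSs", {
  cfg <- small_config(proximal_fraction = 1, proximal_sd = c(0, 0),
                      background_peaks = 0L, hot_peaks = 0L,
                      targets_per_tr = c(10L, 10L))
  uni <- simulate_universe(cfg, seed = 4)
  ds <- simulate_peak_datasets(uni, seed = 5)
  for (d in ds[1:4]) {
    expect_equal(nrow(d$peaks), 10)   # exactly one peak per target
    tgt <- uni$targets[[d$tr_name]]
    mids <- floor((d$peaks$start + d$peaks$end) / 2)
    tss <- uni$annotation$tss[match(tgt, uni$annotation$symbol)]
    expect_setequal(mids, tss)
  }
})

test_that("peak displacement matches the configured Normal distribution", {
  cfg <- small_config(proximal_fraction = 1, proximal_sd = c(400, 400),
                      background_peaks = 0L, hot_peaks = 0L,
                      targets_per_tr = c(60L, 60L), multi_fraction = 0.5,
                      multi_datasets = 4L)
  uni <- simulate_universe(cfg, seed = 9)
  ds <- simulate_peak_datasets(uni, seed = 10)
  d <- unlist(lapply(ds, function(x) {
    tgt_idx <- match(uni$targets[[x$tr_name]], uni$annotation$symbol)
    nt <- nearest_tss(x$peaks, uni$annotation[tgt_idx, , drop = FALSE])
    nt$distance
  }))
  expect_gt(length(d), 1000)
  # E|N(0, sd)| = sd * sqrt(2/pi); folded-normal SD for the 3 SE band
  mu <- 400 * sqrt(2 / pi)
  se <- sqrt(400^2 * (1 - 2 / pi)) / sqrt(length(d))
  expect_lt(abs(mean(d) - mu), 3 * se + 1)  # +1 bp for integer rounding
})

test_that("planted peaks sit closer to target TSSs than background peaks", {
  cfg <- generator_config(n_genes = 400L, n_chroms = 2L, chrom_length = 3e6,
                          n_trs = 34L, targets_per_tr = c(25L, 35L),
                          multi_fraction = 0.5, multi_datasets = 5L,
                          background_peaks = 60L, hot_peaks = 0L)
  uni <- simulate_universe(cfg, seed = 21)
  ds <- simulate_peak_datasets(uni, seed = 22)
  expect_gte(length(ds), 100)
  target_d <- c(); other_d <- c()
  for (x in ds) {
    nt <- nearest_tss(x$peaks, uni$annotation)
    is_target <- nt$gene_symbol %in% uni$targets[[x$tr_name]]
    target_d <- c(target_d, nt$distance[is_target])
    other_d <- c(other_d, nt$distance[!is_target])
  }
  expect_lt(median(target_d), median(other_d))
  expect_lt(wilcox.test(target_d, other_d, alternative = "less")$p.value,
            0.01)
})

test_that("query cases respect noise fractions and composition", {
  bench <- small_bench()
  uni <- bench$universe
  # degenerate: no noise, G = target count -> case genes == the target set
  cfg0 <- small_config(noise_fraction = c("40" = 0),
                       targets_per_tr = c(40L, 40L))
  uni0 <- simulate_universe(cfg0, seed = 3)
  cs0 <- simulate_query_cases(uni0, G = 40, n_cases = 5, seed = 4)
  for (cs in cs0)
    expect_setequal(cs$genes, uni0$targets[[cs$true_tr]])
  # default config noise increases with G
  cfg <- generator_config()
  expect_gt(cfg$noise_fraction[["1000"]], cfg$noise_fraction[["200"]])
  # realized composition: noise fraction close to configured
  cs <- simulate_query_cases(uni, G = 60, n_cases = 10, seed = 5)
  for (x in cs) {
    frac_true <- mean(x$genes %in% uni$targets[[x$true_tr]])
    expect_gte(frac_true, 0.2)
    expect_lte(frac_true, 0.7)
  }
  expect_error(simulate_query_cases(uni, G = 10000, n_cases = 1, seed = 1),
               "exceeds")
})

test_that("signal tracks: assays alternate and informative structure holds", {
  bench <- small_bench()
  tracks <- bench$tracks
  assays <- vapply(tracks, `[[`, "", "assay")
  expect_setequal(unique(assays), c("H3K27ac", "DNase"))
  inf <- attr(tracks, "informative")
  expect_length(inf, small_config()$informative_tracks)

  # all-noise tracks: RP at regulated genes is not elevated
  uni <- bench$universe
  tr0 <- simulate_signal_tracks(uni, n_tracks = 2, seed = 31,
                                n_informative = 0)
  rp <- compute_rp(tr0[[1]], uni$annotation)
  reg <- uni$annotation$symbol %in% unlist(uni$targets)
  p <- wilcox.test(rp[reg], rp[!reg], alternative = "greater")$p.value
  expect_gt(p, 0.001)

  # with unit boost, informative peak signals are drawn from the same
  # distribution as noise-track signals
  tr1 <- simulate_signal_tracks(uni, n_tracks = 2, seed = 32,
                                n_informative = 1)
  uni_b0 <- uni
  uni_b0$config$track_signal_boost <- 1
  tr_b0 <- simulate_signal_tracks(uni_b0, n_tracks = 2, seed = 33,
                                  n_informative = 1)
  ks <- suppressWarnings(ks.test(tr_b0[[1]]$peaks$signal,
                                 tr_b0[[2]]$peaks$signal))
  expect_gt(ks$p.value, 0.001)
  # sanity: with the default boost the informative track is clearly hotter
  expect_gt(mean(tr1[[1]]$peaks$signal), mean(tr1[[2]]$peaks$signal))
})
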