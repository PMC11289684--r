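# Regulatory potential, in-silico deletion, stepwise selection, Cauchy
# combination, AUC, and the Lisa/BART-style rankers.

test_that("compute_rp sums signals with the configured decay", {
  ann <- gene_annotation("g1", "chr1", 50000L)
  ds <- peak_dataset("d", "t", tiny_peaks("chr1", c(49000, 52000),
                                          signal = c(3, 4)))
  expect_equal(unname(compute_rp(ds, ann, window = 10000,
                                 decay = "uniform")["g1"]), 7)
  # one peak exactly one half-life away contributes half its signal
  ds2 <- peak_dataset("d", "t", tiny_peaks("chr1", 51000, signal = 6))
  expect_equal(unname(compute_rp(ds2, ann, window = 10000,
                                 decay = "exponential",
                                 half_life = 1000)["g1"]), 3)
  # outside the window contributes nothing
  ds3 <- peak_dataset("d", "t", tiny_peaks("chr1", 65000, signal = 5))
  expect_equal(unname(compute_rp(ds3, ann, window = 10000)["g1"]), 0)
})

test_that("compute_rp matches a brute-force all-pairs scan", {
  set.seed(19)
  for (rep in 1:12) {
    ann <- random_annotation(40, span = 2e5)
    ds <- random_dataset(ann, n_peaks = 30, span = 2e5)
    w <- 10000; hl <- 1000
    got <- compute_rp(ds, ann, window = w, half_life = hl)
    mid <- floor((ds$peaks$start + ds$peaks$end) / 2)
    for (i in seq_len(nrow(ann))) {
      rp <- 0
      for (j in seq_len(nrow(ds$peaks))) {
        d <- abs(mid[j] - ann$tss[i])
        if (ds$peaks$chrom[j] == ann$chrom[i] && d <= w)
          rp <- rp + ds$peaks$signal[j] * 2^(-d / hl)
      }
      expect_equal(unname(got[ann$symbol[i]]), rp, tolerance = 1e-12)
    }
  }
})

test_that("RP is additive over disjoint peak subsets", {
  set.seed(29)
  ann <- random_annotation(50, span = 2e5)
  ds <- random_dataset(ann, n_peaks = 40, span = 2e5)
  split_at <- 20
  p1 <- ds$peaks[1:split_at, ]
  p2 <- ds$peaks[(split_at + 1):40, ]
  expect_equal(compute_rp(ds$peaks, ann), compute_rp(p1, ann) +
                 compute_rp(p2, ann), tolerance = 1e-12)
})

test_that("in-silico deletion removes exactly the matched signal", {
  ann <- gene_annotation(c("g1", "g2"), "chr1", c(10000L, 80000L))
  track <- signal_track("t1", "H3K27ac",
                        tiny_peaks("chr1", c(9500, 10500, 80000),
                                   signal = c(2, 3, 5)))
  # disjoint TR peaks -> unchanged
  far <- peak_dataset("d", "t", tiny_peaks("chr1", 40000))
  expect_identical(in_silico_delete(track, far, flank = 1000)$peaks,
                   track$peaks)
  # TR peaks covering every track peak -> all signals zero
  all_over <- peak_dataset("d", "t",
                           data.frame(chrom = "chr1", start = 0,
                                      end = 100000))
  expect_true(all(in_silico_delete(track, all_over)$peaks$signal == 0))
  # deletion of everything reproduces RP as the delta
  dr <- delta_rp(track, all_over, ann)
  expect_equal(dr$delta, dr$rp_before)
  expect_true(all(dr$rp_after == 0))
  # delta is never negative on random data
  set.seed(5)
  ann2 <- random_annotation(40, span = 2e5)
  tr2 <- signal_track("t2", "DNase", random_dataset(ann2, 40,
                                                    span = 2e5)$peaks)
  ds2 <- random_dataset(ann2, 15, span = 2e5)
  dr2 <- delta_rp(tr2, ds2, ann2)
  expect_true(all(dr2$delta >= -1e-12))
  expect_error(in_silico_delete(tr2, ds2, flank = -5), ">= 0")
})

test_that("cauchy combination: fixed points, identity and monotonicity", {
  expect_equal(cauchy_combine(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(cauchy_combine(0.37), 0.37, tolerance = 1e-12)
  expect_equal(cauchy_combine(c(0.2, 0.8)), 0.5, tolerance = 1e-12)
  set.seed(6)
  for (rep in 1:50) {
    p <- runif(sample(2:6, 1))
    pc <- cauchy_combine(p)
    expect_true(pc > 0 && pc < 1)
    i <- sample(length(p), 1)
    p2 <- p
    p2[i] <- p[i] * runif(1)      # decrease one component
    expect_lte(cauchy_combine(p2), pc + 1e-12)
  }
  # log-space route agrees with the direct route at moderate p
  for (rep in 1:20) {
    p <- runif(3, 1e-6, 1)
    expect_equal(trbench:::cauchy_combine_log(log(p)),
                 log(cauchy_combine(p, clip = 1e-300)), tolerance = 1e-6)
  }
  # and stays monotone for astronomically small p
  lp <- c(-800, -5, -1)
  lp2 <- c(-900, -5, -1)
  expect_lt(trbench:::cauchy_combine_log(lp2),
            trbench:::cauchy_combine_log(lp))
})

test_that("AUC: separation, reversal, ties, and pROC cross-check", {
  labels <- c(1, 1, 0, 0)
  expect_equal(auc(labels, c(9, 8, 2, 1)), 1)
  expect_equal(auc(labels, c(1, 2, 8, 9)), 0)
  expect_equal(auc(labels, rep(3, 4)), 0.5)
  expect_error(auc(c(1, 1), c(0.3, 0.4)), "both classes")
  set.seed(9)
  for (rep in 1:10) {
    lab <- rbinom(60, 1, 0.4)
    if (length(unique(lab)) < 2) next
    sc <- round(rnorm(60), 1)     # duplicates force the tie correction
    expect_equal(auc(lab, sc),
                 as.numeric(suppressMessages(pROC::auc(lab, sc,
                                                       direction = "<"))))
  }
})

test_that("stepwise selection finds the predictive sample", {
  set.seed(12)
  n <- 400
  y_genes <- sprintf("g%03d", 1:n)
  member <- c(rep(TRUE, 120), rep(FALSE, n - 120))
  # one sample whose RP orders membership perfectly, plus pure noise
  rp <- cbind(signal = c(runif(120, 5, 9), runif(n - 120, 0, 4)),
              noise1 = runif(n), noise2 = runif(n),
              flat = rep(2, n))
  rownames(rp) <- y_genes
  expect_warning(model <- select_predictive_samples(rp, member, max_k = 3),
                 "separation")
  expect_equal(model$samples[1], "signal")
  expect_false("flat" %in% model$samples)     # zero variance never selected
  m1 <- suppressWarnings(select_predictive_samples(rp, member, max_k = 1))
  expect_length(m1$samples, 1)
  expect_error(select_predictive_samples(rp[, 1, drop = FALSE], member),
               "2 samples")
  expect_error(select_predictive_samples(rp, rep(TRUE, n)), "both classes")
})

test_that("lisa-style ranking demotes peakless datasets", {
  bench <- small_bench()
  uni <- bench$universe
  cs <- bench$cases[[1]][[1]]
  empty <- peak_dataset("zz_empty", "ZZTR",
                        data.frame(chrom = character(), start = integer(),
                                   end = integer(), signal = numeric()))
  rk <- lisa_rank(c(bench$datasets[1:10], list(empty)), bench$tracks,
                  uni$annotation, cs, uni$annotation$symbol, max_k = 3)
  expect_equal(nrow(rk), 11)
  # peakless dataset: no deletion, no peak-RP signal -> ranked last or
  # tied-last
  expect_gte(rk$rank[rk$dataset_id == "zz_empty"],
             max(rk$rank) - sum(rk$p == max(rk$p)) + 1)
  expect_true(all(rk$p >= 0 & rk$p <= 1))
  expect_error(lisa_rank(bench$datasets[1:2], bench$tracks, uni$annotation,
                         character(), uni$annotation$symbol), "empty")
})

test_that("bart-style ranking averages its three component ranks", {
  bench <- small_bench()
  uni <- bench$universe
  cs <- bench$cases[[1]][[2]]
  rk <- bart_rank(bench$datasets, bench$tracks, uni$annotation, cs,
                  uni$annotation$symbol, max_k = 3, n_null_sets = 10,
                  seed = 4)
  expect_equal(nrow(rk), nrow(uni$trs))       # one term per TR
  expect_true(all(rk$max_auc >= 0 & rk$max_auc <= 1))
  # the reported average equals the manual mean of the component ranks and
  # determines the final order
  expect_equal(rk$avg_rank, (rk$rank_auc + rk$rank_p + rk$rank_z) / 3)
  expect_false(is.unsorted(rk$avg_rank))
  for (col in c("rank_auc", "rank_p", "rank_z"))
    expect_setequal(rk[[col]], seq_len(nrow(rk)))
})

test_that("a dominant TR is ranked first by the bart-style ranker", {
  # engineered universe: TR "AAA" binds exactly the high-signal sites
  set.seed(44)
  n <- 120
  ann <- gene_annotation(sprintf("g%03d", 1:n), "chr1",
                         as.integer(seq(5000, 1.2e6, length.out = n)))
  hi <- ann$tss[1:40]
  lo <- ann$tss[81:120]
  tracks <- list(
    signal_track("h1", "H3K27ac",
                 tiny_peaks("chr1", c(hi, lo), width = 400,
                            signal = c(rep(8, 40), rep(0.5, 40)))),
    signal_track("d1", "DNase",
                 tiny_peaks("chr1", c(hi, lo), width = 400,
                            signal = c(rep(7, 40), rep(0.4, 40)))))
  datasets <- list(
    peak_dataset("a1", "AAA", tiny_peaks("chr1", hi, width = 300)),
    peak_dataset("b1", "BBB", tiny_peaks("chr1", lo, width = 300)),
    peak_dataset("c1", "CCC",
                 tiny_peaks("chr1", ann$tss[sample.int(n, 40)] + 25000,
                            width = 300)))
  rk <- suppressWarnings(
    bart_rank(datasets, tracks, ann, query = ann$symbol[1:40],
              background = ann$symbol, max_k = 2, n_null_sets = 10,
              seed = 2))
  expect_equal(rk$tr_name[1], "AAA")
})
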