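# Promoter-proportion testing, per-gene max-signal profiles, K-S ranking
# and the fast interval paths against their GRanges references.

test_that("promoter classification nests with window size", {
  bench <- small_bench()
  uni <- bench$universe
  ds <- bench$datasets[[1]]
  bg <- uni$annotation$symbol
  set.seed(2)
  q <- sample(bg, 60)
  counts <- vapply(c(1000, 2000, 4000, 8000), function(up) {
    p <- promoter_proportion_test(ds, uni$annotation, q, bg, upstream = up,
                                  downstream = up / 10)
    sum(attr(p, "counts")[1:2])
  }, 0)
  expect_true(all(diff(counts) >= 0))
})

test_that("promoter-proportion test handles boundary and degenerate cases", {
  ann <- gene_annotation(c("q1", "b1"), "chr1", c(10000L, 60000L))
  # all peaks in the query promoter, balanced reference
  ds <- peak_dataset("d", "t", tiny_peaks("chr1", c(9800, 10100, 9900)))
  ref <- tiny_peaks("chr1", c(9900, 60000, 10050, 59950))
  p <- promoter_proportion_test(ds, ann, "q1", c("q1", "b1"),
                                upstream = 1000, downstream = 500,
                                alternative = "greater", reference = ref)
  expect_lt(as.numeric(p), 0.51)
  # proportions equal to the reference -> two-sided p = 1 on balanced table
  ds_bal <- peak_dataset("d", "t", tiny_peaks("chr1", c(9900, 60000)))
  p_bal <- promoter_proportion_test(ds_bal, ann, "q1", c("q1", "b1"),
                                    upstream = 1000, downstream = 500,
                                    reference = ref)
  expect_equal(as.numeric(p_bal), 1)
  # zero peaks -> warning, p = 1
  ds0 <- peak_dataset("d0", "t",
                      data.frame(chrom = character(), start = integer(),
                                 end = integer(), signal = numeric()))
  expect_warning(p0 <- promoter_proportion_test(ds0, ann, "q1",
                                                c("q1", "b1")),
                 "no peaks")
  expect_equal(as.numeric(p0), 1)
})

test_that("gene_max_signal takes the max and defaults to zero", {
  ann <- gene_annotation(c("g1", "g2"), "chr1", c(10000L, 90000L))
  ds <- peak_dataset("d", "t", tiny_peaks("chr1", c(9500, 10500, 50000),
                                          signal = c(2, 7, 9)))
  prof <- gene_max_signal(ds, ann, window = 2000)
  expect_equal(unname(prof["g1"]), 7)
  expect_equal(unname(prof["g2"]), 0)
})

test_that("gene_max_signal agrees with a brute-force per-gene scan", {
  set.seed(31)
  for (rep in 1:15) {
    ann <- random_annotation(50, span = 3e5)
    ds <- random_dataset(ann, n_peaks = 35, span = 3e5)
    w <- sample(c(2000, 5000, 12000), 1)
    got <- gene_max_signal(ds, ann, window = w)
    for (i in seq_len(nrow(ann))) {
      lo <- ann$tss[i] - w
      hi <- ann$tss[i] + w          # window [lo, hi) half-open
      best <- 0
      for (j in seq_len(nrow(ds$peaks))) {
        if (ds$peaks$chrom[j] == ann$chrom[i] &&
            ds$peaks$start[j] < hi && ds$peaks$end[j] > lo)
          best <- max(best, ds$peaks$signal[j])
      }
      expect_equal(unname(got[ann$symbol[i]]), best)
    }
  }
})

test_that("K-S ranking: boundary statistics and brute-force eCDF oracle", {
  bg <- sprintf("g%02d", 1:40)
  q <- bg[1:10]
  # query signals strictly above background -> D = 1
  prof_hi <- setNames(c(rep(10, 10), runif(30)), bg)
  # identical constant profile -> D = 0, p = 1
  prof_eq <- setNames(rep(1, 40), bg)
  rl <- ks_rank(list(hi = prof_hi, eq = prof_eq), c("A", "B"), q, bg)
  expect_equal(unname(rl$D[rl$dataset_id == "hi"]), 1)
  expect_equal(unname(rl$D[rl$dataset_id == "eq"]), 0)
  expect_equal(unname(rl$p[rl$dataset_id == "eq"]), 1)
  expect_equal(rl$dataset_id[1], "hi")

  set.seed(17)
  for (rep in 1:25) {
    prof <- setNames(c(rnorm(10, sample(0:2, 1)), rnorm(30)), bg)
    rlr <- ks_rank(list(d = prof), "T", q, bg)
    # brute-force sup-difference of the two eCDFs
    x <- prof[q]; y <- prof[setdiff(bg, q)]
    grid <- sort(c(x, y))
    D <- max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), 0)))
    expect_equal(unname(rlr$D), D, tolerance = 1e-12)
  }
})

test_that("scaling factor: equality gives 1, sparse profiles stay clamped", {
  bg <- sprintf("g%02d", 1:30)
  q <- bg[1:10]
  same <- setNames(rep(c(5, 1, 1), 10), bg)   # identical top-5% means
  prof_q0 <- setNames(c(rep(0, 10), rep(3, 20)), bg)
  rl <- ks_rank(list(a = same, b = prof_q0), c("A", "B"), q, bg)
  expect_true(all(rl$score >= 0))
  # direct check of the factor
  expect_equal(trbench:::signal_scaling_factor(c(5, 1), c(5, 1)), 1)
  expect_equal(trbench:::signal_scaling_factor(c(9, 9), c(0, 0)), 1e3)
  expect_equal(trbench:::signal_scaling_factor(rep(1e-9, 5), rep(1, 5)), 1e-3)
})

test_that("MAGIC-style ranking places the planted TR above the median", {
  bench <- default_bench()
  uni <- bench$universe
  cases <- bench$cases[["200"]][1:20]
  above <- vapply(seq_along(cases), function(i) {
    rk <- magic_rank(bench$datasets, uni$annotation, cases[[i]],
                     uni$annotation$symbol)
    best_rank_of(rk, cases[[i]]$true_tr) < nrow(rk) / 2
  }, logical(1))
  expect_gte(mean(above), 0.9)
})

test_that("fast interval paths agree with the GRanges route", {
  set.seed(41)
  for (rep in 1:10) {
    ann <- random_annotation(60, span = 2e5)
    ds <- random_dataset(ann, n_peaks = 50, span = 2e5)
    # max signal: fast vs naive covered above; here fast_rp vs compute_rp's
    # own GRanges-based contribution route
    tidx <- trbench:::tss_index(ann)
    rp_fast <- trbench:::fast_rp(ds$peaks, tidx, nrow(ann), 10000,
                                 "exponential", 1000)
    rp_ref <- compute_rp(ds, ann, window = 10000, half_life = 1000)
    expect_equal(unname(rp_ref), rp_fast, tolerance = 1e-12)
    # overlapping_peaks vs countOverlaps
    other <- random_dataset(ann, n_peaks = 20, span = 2e5)
    gr <- GenomicRanges::reduce(trbench:::peaks_granges(other$peaks))
    midx <- trbench:::merged_interval_index(gr)
    got <- trbench:::overlapping_peaks(ds$peaks, midx)
    want <- which(GenomicRanges::countOverlaps(
      trbench:::peaks_granges(ds$peaks), gr) > 0)
    expect_identical(got, want)
  }
})
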