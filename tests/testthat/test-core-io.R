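# Domain types, file round-trips and interval semantics.

test_that("annotation reader parses rows and enforces invariants", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("symbol\tchrom\ttss\tstrand",
               "GATA1\tchr1\t5000\t+",
               "TAL1\tchr2\t900\t-"), path)
  ann <- read_annotation(path)
  expect_s3_class(ann, "gene_annotation")
  expect_equal(ann$tss, c(5000L, 900L))
  expect_equal(ann$strand, c("+", "-"))

  writeLines(c("symbol\tchrom\ttss\tstrand",
               "GATA1\tchr1\t5000\t+",
               "GATA1\tchr2\t900\t-"), path)
  expect_error(read_annotation(path), "duplicate")

  writeLines(c("symbol\tchrom\ttss\tstrand",
               "GATA1\tchr1\t5000"), path)
  expect_error(read_annotation(path), "line 2")

  writeLines("symbol\tchrom\ttss\tstrand", path)
  expect_warning(ann0 <- read_annotation(path), "empty")
  expect_equal(nrow(ann0), 0)
})

test_that("annotation writer round-trips", {
  ann <- tiny_annotation()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  expect_equal(as.data.frame(read_annotation(path)), as.data.frame(ann))
})

test_that("BED peak reader parses signal and validates intervals", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tp1\t5", "chr2\t0\t50"), path)
  ds <- read_peaks(path, "d1", "GATA1")
  expect_equal(ds$peaks$start, c(100L, 0L))
  expect_equal(ds$peaks$end, c(200L, 50L))
  expect_equal(ds$peaks$signal, c(5, 1))   # missing score column -> 1

  writeLines("chr1\t200\t100", path)
  expect_error(read_peaks(path, "d1", "x"), "start must be <")
  expect_error(peak_dataset("d", "t", data.frame(chrom = "chr1", start = -5,
                                                 end = 10)),
               "non-negative")
})

test_that("peak write/read round-trip preserves interval fields exactly", {
  set.seed(1)
  ds <- random_dataset(tiny_annotation(), n_peaks = 25, span = 9e4)
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks(ds, path)
  back <- read_peaks(path, ds$dataset_id, ds$tr_name)
  expect_identical(back$peaks$start, ds$peaks$start)
  expect_identical(back$peaks$end, ds$peaks$end)
  expect_equal(back$peaks$signal, ds$peaks$signal)
})

test_that("GMT gene sets parse, validate and round-trip in order", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("case1\tGATA1\tg2\tg1\tg3", path)
  cases <- read_gene_sets(path)
  expect_equal(cases[[1]]$true_tr, "GATA1")
  expect_equal(cases[[1]]$genes, c("g2", "g1", "g3"))  # order preserved

  writeLines("case1\tGATA1", path)
  expect_error(read_gene_sets(path), "fewer than 3")

  writeLines("case1\tGATA1\tg1\tg1", path)
  expect_error(read_gene_sets(path), "duplicate")

  cs <- list(query_case("a", c("g1", "g9", "g4"), "TAL1"),
             query_case("b", c("g2", "g3"), "SPI1"))
  write_gene_sets(cs, path)
  back <- read_gene_sets(path)
  expect_equal(back[[1]]$genes, cs[[1]]$genes)
  expect_equal(back[[2]]$true_tr, "SPI1")
})

test_that("ranking list TSV round-trips", {
  rl <- rank_datasets(data.frame(dataset_id = c("d2", "d1"),
                                 tr_name = c("B", "A"), p = c(0.2, 0.01)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking(rl, path)
  back <- read_ranking(path)
  expect_equal(back$tr_name, rl$tr_name)
  expect_equal(back$p, rl$p)
})

test_that("query case invariants hold", {
  expect_error(query_case("c", c("g1", "g1"), "T"), "duplicate")
  cs <- query_case("c", sprintf("g%d", 1:10), "T")
  expect_equal(truncate_case(cs, 4)$genes, cs$genes[1:4])
  expect_error(truncate_case(cs, 11), "cannot truncate")
})

test_that("half-open interval semantics: [100,200) does not touch [200,300)", {
  ann <- gene_annotation("g1", "chr1", 250L)   # window 50 -> [200, 300)
  ds <- peak_dataset("d", "t", data.frame(chrom = "chr1", start = 100,
                                          end = 200))
  expect_length(assign_targets_window(ds, ann, 50)$genes, 0)
  # one bp further right it overlaps
  ds2 <- peak_dataset("d", "t", data.frame(chrom = "chr1", start = 100,
                                           end = 201))
  expect_equal(assign_targets_window(ds2, ann, 50)$genes, "g1")
})

test_that("nearest TSS handles midpoints, ties and absent chromosomes", {
  ann <- gene_annotation(c("b", "a", "z"), c("chr1", "chr1", "chr1"),
                         c(100L, 210L, 400L))
  # midpoint 150: TSSs at 100 (d=50) and 210 (d=60) -> gene "b"
  res <- nearest_tss_distance(list(chrom = "chr1", start = 100, end = 200),
                              ann)
  expect_equal(res$gene_symbol, "b")
  expect_equal(res$distance, 50)
  # exact TSS hit -> distance 0
  res0 <- nearest_tss_distance(list(chrom = "chr1", start = 380, end = 420),
                               ann)
  expect_equal(res0, list(gene_symbol = "z", distance = 0))
  # equidistant -> lexicographically smaller symbol
  ann2 <- gene_annotation(c("b", "a"), "chr1", c(100L, 200L))
  tie <- nearest_tss_distance(list(chrom = "chr1", start = 100, end = 200),
                              ann2)
  expect_equal(tie$gene_symbol, "a")
  # absent chromosome skipped with warning
  expect_warning(
    out <- nearest_tss_distance(list(chrom = "chrX", start = 1, end = 10),
                                ann),
    "skipped")
  expect_null(out)
})

test_that("nearest_tss agrees with exhaustive scan on random annotations", {
  set.seed(42)
  for (rep in 1:15) {
    ann <- random_annotation(sample(5:200, 1), n_chroms = 2, span = 1e5)
    peaks <- tiny_peaks(sample(unique(ann$chrom), 30, replace = TRUE),
                        sample.int(99000, 30) + 400)
    got <- nearest_tss(peaks, ann)
    mid <- floor((peaks$start + peaks$end) / 2)
    for (i in seq_len(nrow(peaks))) {
      cand <- ann[ann$chrom == peaks$chrom[i], , drop = FALSE]
      d <- abs(cand$tss - mid[i])
      dmin <- min(d)
      best <- min(cand$symbol[d == dmin])
      expect_identical(got$gene_symbol[i], best)
      expect_identical(got$distance[i], as.integer(dmin))
    }
  }
})
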