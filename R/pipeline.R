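# Pipeline orchestration: simulate -> build-library -> rank -> evaluate ->
# combine -> bias, from a single config and root seed, with a JSON run
# manifest. All randomness flows from the root seed via named substreams.

#' Derive a named substream seed from a root seed
#'
#' Deterministic hash of `(seed, name)` kept below 2^31 so that independent
#' pipeline stages never share RNG streams.
#'
#' @param seed Root integer seed.
#' @param name Substream name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

#' Shuffle a ranking list (random-permutation baseline)
#'
#' Randomly permutes the terms of a ranking and reassigns ranks 1..L; the
#' no-information baseline against which planted-TR recovery is compared.
#'
#' @param ranking A [ranking_list()].
#' @param seed Integer seed.
#' @return A permuted [ranking_list()].
#' @export
permute_ranking <- function(ranking, seed = 1L) {
  set.seed(seed)
  df <- as.data.frame(ranking)
  df <- df[sample.int(nrow(df)), , drop = FALSE]
  df$rank <- NULL
  df$q <- NULL
  ranking_list(df)
}

known_stages <- c("simulate", "build_library", "rank", "evaluate",
                  "combine", "bias")
known_rankers <- c("window_fisher", "nearest_fisher", "density_fisher",
                   "chipatlas", "magic", "lisa", "bart")

validate_pipeline_config <- function(config) {
  stages <- config$stages
  if (is.null(stages)) stages <- known_stages
  bad <- setdiff(stages, known_stages)
  if (length(bad))
    stop("config field 'stages' contains unknown stage(s): ",
         paste(bad, collapse = ", "))
  rankers <- config$rankers
  if (is.null(rankers)) rankers <- "window_fisher"
  bad <- setdiff(rankers, known_rankers)
  if (length(bad))
    stop("config field 'rankers' contains unknown ranker(s): ",
         paste(bad, collapse = ", "))
  config$stages <- stages
  config$rankers <- rankers
  if (is.null(config$G)) config$G <- 200L
  if (is.null(config$n_cases)) config$n_cases <- 20L
  if (is.null(config$K)) config$K <- c(10L, 50L, 100L)
  if (is.null(config$library))
    config$library <- list(method = "window", window = 2000)
  config
}

# one ranking list per case for a named ranker
run_ranker <- function(name, bench, config) {
  ann <- bench$universe$annotation
  bg <- ann$symbol
  cases <- bench$cases[[1L]]
  switch(
    name,
    window_fisher = {
      lib <- build_target_library(bench$datasets, ann, "window",
                                  window = config$library$window %||% 2000)
      rank_library_cases(lib, cases, bg)
    },
    nearest_fisher = {
      lib <- build_target_library(bench$datasets, ann, "nearest",
                                  n_genes = config$library$n_genes %||% 500)
      rank_library_cases(lib, cases, bg)
    },
    density_fisher = {
      lib <- build_target_library(bench$datasets, ann, "density",
                                  range_bp = config$library$range_bp %||% 1e4)
      rank_library_cases(lib, cases, bg)
    },
    chipatlas = lapply(cases, function(cs)
      chipatlas_rank(bench$datasets, ann, cs, bg)),
    magic = lapply(cases, function(cs)
      magic_rank(bench$datasets, ann, cs, bg)),
    lisa = lapply(cases, function(cs)
      lisa_rank(bench$datasets, bench$tracks, ann, cs, bg,
                max_k = config$max_k %||% 5L)),
    bart = lapply(cases, function(cs)
      bart_rank(bench$datasets, bench$tracks, ann, cs, bg,
                max_k = config$max_k %||% 5L,
                n_null_sets = config$n_null_sets %||% 20L,
                seed = substream_seed(bench$seed, "bart_null"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full benchmark pipeline
#'
#' Executes the configured stage list against a synthetic universe and
#' writes every stage's outputs plus a run manifest under `outdir`.
#' Deterministic given `(config, seed)`.
#'
#' @param config Path to a YAML config file, or a config list. Recognized
#'   fields: `stages` (subset of simulate, build_library, rank, evaluate,
#'   combine, bias), `rankers`, `generator` (overrides for
#'   [generator_config()]), `G`, `n_cases`, `K`, `library` (method and its
#'   cutoff), `max_k`, `n_null_sets`.
#' @param seed Root integer seed.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), seed = 1L, outdir = tempfile()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gen_args <- config$generator %||% list()
  gcfg <- do.call(generator_config, gen_args)
  manifest <- list(seed = as.integer(seed), config = config,
                   package_version = as.character(
                     utils::packageVersion("trbench")),
                   stages_run = character(0))

  bench <- simulate_benchmark(gcfg, seed, G = config$G[1],
                              n_cases = config$n_cases)
  if ("simulate" %in% config$stages) {
    write_annotation(bench$universe$annotation,
                     file.path(outdir, "annotation.tsv"))
    write_gene_sets(bench$cases[[1L]], file.path(outdir, "cases.gmt"))
    bed_dir <- file.path(outdir, "datasets")
    dir.create(bed_dir, showWarnings = FALSE)
    for (ds in bench$datasets)
      write_peaks(ds, file.path(bed_dir, paste0(ds$dataset_id, ".bed")))
    track_dir <- file.path(outdir, "tracks")
    dir.create(track_dir, showWarnings = FALSE)
    for (tk in bench$tracks)
      write_peaks(tk, file.path(track_dir, paste0(tk$sample_id, ".bed")))
    manifest$stages_run <- c(manifest$stages_run, "simulate")
  }
  if ("build_library" %in% config$stages) {
    wanted <- switch(config$library$method, window = "window",
                     nearest = "n_genes",
                     density = c("range_bp", "quantile"))
    lib_args <- config$library[intersect(names(config$library), wanted)]
    lib <- do.call(build_target_library,
                   c(list(bench$datasets, bench$universe$annotation,
                          config$library$method),
                     lib_args))
    write_target_library(lib, file.path(outdir, "library.tsv"))
    manifest$stages_run <- c(manifest$stages_run, "build_library")
  }
  rankings <- NULL
  if ("rank" %in% config$stages) {
    rankings <- lapply(config$rankers, run_ranker, bench = bench,
                       config = config)
    names(rankings) <- config$rankers
    for (rn in config$rankers) {
      rdir <- file.path(outdir, "rankings", rn)
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      for (cid in names(rankings[[rn]]))
        write_ranking(rankings[[rn]][[cid]],
                      file.path(rdir, paste0(cid, ".tsv")))
    }
    manifest$stages_run <- c(manifest$stages_run, "rank")
  }
  truth <- vapply(bench$cases[[1L]], `[[`, "", "true_tr")
  if ("evaluate" %in% config$stages && !is.null(rankings)) {
    metrics <- do.call(rbind, lapply(names(rankings), function(rn)
      cbind(ranker = rn,
            metric_report(rankings[[rn]], truth, K = config$K))))
    write.table(metrics, file.path(outdir, "metrics.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages_run <- c(manifest$stages_run, "evaluate")
  }
  if ("combine" %in% config$stages && length(rankings) >= 2) {
    pairs <- utils::combn(names(rankings), 2, simplify = FALSE)
    comb <- do.call(rbind, lapply(pairs, function(pr) {
      cp <- combine_pair(rankings[[pr[1]]], rankings[[pr[2]]], truth,
                         K = config$K)
      jac <- vapply(config$K, function(k)
        mean(vapply(seq_along(truth), function(i)
          jaccard_topk(rankings[[pr[1]]][[i]], rankings[[pr[2]]][[i]], k),
          0)), 0)
      cbind(method_a = pr[1], method_b = pr[2], cp$by_K, jaccard = jac)
    }))
    write.table(comb, file.path(outdir, "combine.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$stages_run <- c(manifest$stages_run, "combine")
  }
  if ("bias" %in% config$stages && !is.null(rankings)) {
    trs <- bench$universe$trs
    multi <- trs$tr_name[trs$n_datasets > 1]
    single <- trs$tr_name[trs$n_datasets == 1]
    if (length(multi) && length(single)) {
      # exclusion of perturbed-target lists can empty small runs; fall back
      # to using every list in that case
      br <- if (all(truth %in% c(multi, single)))
        bias_analysis(rankings[[1L]], multi, single)
      else
        bias_analysis(rankings[[1L]], multi, single, truth = truth)
      jsonlite::write_json(
        list(ranker = names(rankings)[1], I = br$I, Z_c = br$Z_c,
             p_c = br$p_c, excluded = br$excluded),
        file.path(outdir, "bias.json"), auto_unbox = TRUE, digits = NA)
      manifest$stages_run <- c(manifest$stages_run, "bias")
    }
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
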