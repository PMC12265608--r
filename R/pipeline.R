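#' Validate a pipeline run configuration
#'
#' A run config is a YAML (or equivalent list) with top-level keys
#' `seed` (integer), `out_dir` (created if absent) and `stages` — an
#' ordered list of stage blocks, each with a `stage` name
#' (`simulate`, `split`, `compress`, `probe`, `aggregate`, `compose`)
#' plus that stage's parameters. Unknown top-level keys and unknown stage
#' names are rejected before anything runs.
#'
#' @param config List or path to a YAML file.
#' @return The validated config list (class `"run_config"`).
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known_top <- c("seed", "out_dir", "stages")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config needs an integer 'seed'")
  if (is.null(config$out_dir)) stop("config needs 'out_dir'")
  if (is.null(config$stages) || !length(config$stages))
    stop("config needs a non-empty 'stages' list")
  known_stages <- c("simulate", "split", "compress", "probe", "aggregate",
                    "compose")
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.null(st$stage))
      stop("stage block ", i, " lacks a 'stage' name")
    if (!st$stage %in% known_stages)
      stop("unknown stage '", st$stage, "' (block ", i, ")")
  }
  structure(config, class = c("run_config", "list"))
}

provenance_lines <- function(stage, seed, params) {
  kv <- paste(names(params),
              vapply(params, function(p) paste(format(p), collapse = ","),
                     character(1)),
              sep = "=", collapse = " ")
  c(paste0("# txbench ", as.character(utils::packageVersion("txbench")),
           " stage=", stage, " seed=", seed),
    paste0("# params: ", kv))
}

write_stage_tsv <- function(df, path, stage, seed, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(stage, seed, params), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Execute a benchmarking pipeline from a config
#'
#' Stages run in declared order; every output table carries `#`-prefixed
#' provenance lines (package version, stage seed, parameters) so a result
#' file is self-describing. One top-level seed deterministically derives a
#' per-stage seed via [derive_seed()], so reruns of the same config are
#' byte-identical and stages can be reproduced in isolation. Any stage
#' error aborts the run, naming the failing stage.
#'
#' @param config List or YAML path accepted by [validate_run_config()].
#' @param only Optional stage name: run only stage blocks of that kind
#'   (the CLI subcommands map onto this).
#' @return Invisibly, a data frame logging per-stage timing, outputs and
#'   record counts.
#' @export
run_pipeline <- function(config, only = NULL) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (!is.null(only) && st$stage != only) next
    stage_seed <- derive_seed(config$seed, paste0(st$stage, i))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      run_stage(st, stage_seed, config$out_dir),
      error = function(e)
        stop("stage '", st$stage, "' (block ", i, ") failed: ",
             conditionMessage(e), call. = FALSE))
    log[[length(log) + 1L]] <- data.frame(
      stage = st$stage, block = i, seed = stage_seed,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      records = res$records, outputs = paste(res$outputs, collapse = ","))
    message(sprintf("[txbench] %-9s block %d: %d record(s) -> %s",
                    st$stage, i, res$records,
                    paste(res$outputs, collapse = ", ")))
  }
  invisible(do.call(rbind, log))
}

run_stage <- function(st, seed, out_dir) {
  p <- function(f) file.path(out_dir, f)
  switch(st$stage,
    simulate = {
      n <- st$n %||% 100L
      len <- st$length %||% 200L
      spec <- region_grammar_spec(st$region %||% "uniform")
      seqs <- simulate_markov_region(spec, n, c(len, len), seed)
      names(seqs) <- sprintf("tx%04d", seq_len(n))
      tx <- lapply(names(seqs), function(id) transcript(id, seqs[[id]]))
      fa <- p(st$out_fasta %||% "transcripts.fasta")
      write_fasta(tx, fa)
      outs <- fa
      if (!is.null(st$motif)) {
        task <- task_spec("motif", st$task_kind %||% "binary")
        lab <- simulate_motif_labels(seqs, st$motif, task,
                                     effect = st$effect %||% 1,
                                     noise_sd = st$noise_sd %||% 0,
                                     seed = seed)
        lt <- p(st$out_labels %||% "labels.tsv")
        write_stage_tsv(lab, lt, "simulate", seed, st[names(st) != "stage"])
        outs <- c(outs, lt)
      }
      list(records = n, outputs = outs)
    },
    split = {
      tx <- read_fasta(p(st$fasta %||% "transcripts.fasta"))
      ids <- vapply(tx, `[[`, character(1), "id")
      seqs <- setNames(vapply(tx, `[[`, character(1), "sequence"), ids)
      strategy <- st$strategy %||% "random"
      sp <- switch(strategy,
        random = random_split(ids, st$test_frac %||% 0.2, seed),
        chromosome = chromosome_split(tx, st$held_out),
        kmer = kmer_cluster_split(seqs, k = st$k %||% 5,
                                  n_clusters = st$n_clusters,
                                  test_frac = st$test_frac %||% 0.2,
                                  seed = seed),
        homology = homology_split(tx,
                                  read_paralog_edges(p(st$edges)),
                                  identity_threshold = st$threshold %||% 0.35,
                                  test_frac = st$test_frac %||% 0.2,
                                  seed = seed),
        stop("unknown split strategy '", strategy, "'"))
      out <- p(st$out %||% "split.tsv")
      write_split_tsv(sp, out)
      list(records = length(sp$assignment), outputs = out)
    },
    compress = {
      if (is.null(st$regions) || length(st$regions) < 2L)
        stop("compress stage needs >= 2 named 'regions' FASTA paths")
      corpora <- lapply(st$regions, function(f)
        vapply(read_fasta(p(f)), `[[`, character(1), "sequence"))
      cc <- cross_compression_matrix(corpora, k = st$k %||% 3,
                                     pseudo_count = st$pseudo_count %||% 1)
      f1 <- p(st$out_ratios %||% "compression_ratios.tsv")
      f2 <- p(st$out_percent %||% "compression_percent_increase.tsv")
      prm <- st[!names(st) %in% c("stage", "regions")]
      write_stage_tsv(as.data.frame(cc$ratios), f1, "compress", seed, prm)
      write_stage_tsv(as.data.frame(round(cc$percent_increase, 4)), f2,
                      "compress", seed, prm)
      list(records = length(corpora)^2, outputs = c(f1, f2))
    },
    probe = {
      tx <- read_fasta(p(st$fasta %||% "transcripts.fasta"))
      task <- task_spec(st$task_name %||% "task",
                        st$task_kind %||% "binary",
                        locality = st$locality %||% "local")
      labels <- read_label_table(p(st$labels %||% "labels.tsv"), task)
      ds <- labeled_dataset(tx, labels, task)
      k <- st$k %||% 4
      embedder <- function(trs) {
        s <- setNames(vapply(trs, `[[`, character(1), "sequence"),
                      vapply(trs, `[[`, character(1), "id"))
        kmer_count_embed(s, k)
      }
      splitter <- function(d, s)
        random_split(vapply(d$transcripts, `[[`, character(1), "id"),
                     st$test_frac %||% 0.2, s)
      tab <- run_benchmark_protocol(ds, embedder, splitter,
                                    n_seeds = st$n_seeds %||% 10,
                                    regularization = st$regularization %||% 1,
                                    model_name = st$model_name %||%
                                      paste0("kmer", k))
      out <- p(st$out %||% "scores.tsv")
      write_stage_tsv(tab, out, "probe", seed, st[names(st) != "stage"])
      list(records = nrow(tab), outputs = out)
    },
    aggregate = {
      sc <- do.call(rbind, lapply(st$scores, function(f)
        read.delim(p(f), comment.char = "#", stringsAsFactors = FALSE)))
      z <- zscore_within_dataset(score_table(sc))
      overall <- overall_model_score(z)
      out <- p(st$out %||% "overall.tsv")
      write_stage_tsv(overall, out, "aggregate", seed,
                      st[names(st) != "stage"])
      list(records = nrow(overall), outputs = out)
    },
    compose = {
      tx <- read_fasta(p(st$utrs %||% "utrs.fasta"))
      ann <- do.call(rbind, lapply(tx, function(t) {
        if (is.null(t$cds)) stop("transcript ", t$id, " lacks a CDS")
        cbind(id = t$id, annotate_utr(t$sequence, t$cds[1]))
      }))
      sp <- build_compositional_split(ann)
      out <- p(st$out %||% "compositional_split.tsv")
      write_split_tsv(sp, out)
      list(records = nrow(ann), outputs = out)
    })
}
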