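#' Assemble and validate a score table
#'
#' The long-format container every aggregation step consumes: one metric
#' value per (model, dataset, subtask, seed).
#'
#' @param df Data frame with columns `model`, `dataset`, `subtask`,
#'   `seed`, `metric`, `value`.
#' @return `df` classed `"score_table"`; errors on duplicate keys.
#' @export
score_table <- function(df) {
  need <- c("model", "dataset", "subtask", "seed", "metric", "value")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("score table missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(df$model, df$dataset, df$subtask, df$seed)
  if (anyDuplicated(key))
    stop("duplicate (model, dataset, subtask, seed) record")
  class(df) <- c("score_table", "data.frame")
  df
}

#' Fisher variance-stabilizing transform of a correlation
#'
#' `atanh(r) = 0.5 * log((1 + r) / (1 - r))`. Applied to Pearson metrics
#' before any averaging or Z-scoring, because raw correlations compress
#' near +/-1.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return Transformed value(s); inverse is `tanh`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z requires |r| < 1")
  0.5 * log((1 + r) / (1 - r))
}

#' Z-score model performances within each dataset
#'
#' Subtask and seed values are first mean-aggregated to one value per
#' (model, dataset) — Pearson metrics are Fisher-transformed before the
#' mean — then each dataset's model scores are centred and scaled by
#' their sample standard deviation (n-1), so every dataset contributes on
#' the same scale regardless of its metric.
#'
#' @param table A [score_table()] (or compatible data frame).
#' @return Data frame `model`, `dataset`, `z`, plus the aggregated
#'   pre-Z value as `score`. Errors if any dataset has a single model or
#'   zero variance across models.
#' @export
zscore_within_dataset <- function(table) {
  stopifnot(is.data.frame(table))
  v <- table$value
  pearson <- table$metric == "pearson_r"
  v[pearson] <- fisher_z(v[pearson])
  agg <- aggregate(v, by = list(model = table$model,
                                dataset = table$dataset), FUN = mean)
  names(agg)[3] <- "score"
  out <- do.call(rbind, lapply(split(agg, agg$dataset), function(d) {
    if (nrow(d) < 2L)
      stop("dataset '", d$dataset[1], "' has a single model: z undefined")
    s <- sd(d$score)
    if (s == 0)
      stop("zero variance across models in dataset '", d$dataset[1], "'")
    d$z <- (d$score - mean(d$score)) / s
    d
  }))
  rownames(out) <- NULL
  out
}

#' Overall model score: mean Z across datasets
#'
#' @param z_table Output of [zscore_within_dataset()].
#' @return Data frame `model`, `overall_z`, `n_datasets`,
#'   `n_datasets_missing` (relative to the union of datasets present).
#' @export
overall_model_score <- function(z_table) {
  all_ds <- unique(z_table$dataset)
  by_model <- split(z_table, z_table$model)
  data.frame(
    model = names(by_model),
    overall_z = vapply(by_model, function(d) mean(d$z), numeric(1)),
    n_datasets = vapply(by_model, nrow, integer(1)),
    n_datasets_missing = vapply(by_model, function(d)
      length(setdiff(all_ds, d$dataset)), integer(1)),
    row.names = NULL)
}

#' Global-versus-local task bias of each model
#'
#' Contrastively pre-trained models tend to over-perform on global
#' (transcript-level) tasks and under-perform on local (nucleotide-level)
#' ones. The bias statistic is the mean Z-score over global datasets minus
#' the mean over local datasets; positive values indicate a global-task
#' tilt, and swapping the locality labels negates it.
#'
#' @param z_table Output of [zscore_within_dataset()].
#' @param locality_map Named character vector dataset -> `"global"` /
#'   `"local"`; both classes must be represented.
#' @return Data frame `model`, `bias` (`NA`, with a warning, for models
#'   absent from one class).
#' @export
global_task_bias <- function(z_table, locality_map) {
  loc <- locality_map[z_table$dataset]
  if (anyNA(loc))
    stop("locality missing for dataset(s): ",
         paste(unique(z_table$dataset[is.na(loc)]), collapse = ", "))
  if (length(unique(loc)) < 2L)
    stop("need at least one dataset in each locality class")
  by_model <- split(data.frame(z = z_table$z, loc = loc), z_table$model)
  bias <- vapply(by_model, function(d) {
    if (!all(c("global", "local") %in% d$loc)) return(NA_real_)
    mean(d$z[d$loc == "global"]) - mean(d$z[d$loc == "local"])
  }, numeric(1))
  if (anyNA(bias))
    warning("bias undefined for model(s) absent from one locality class: ",
            paste(names(bias)[is.na(bias)], collapse = ", "))
  data.frame(model = names(by_model), bias = unname(bias))
}

#' Percent metric decrease of a splitting strategy versus random
#'
#' For each subtask, `100 * (random - strategy) / random`: how much of the
#' random-split score evaporates when evaluation controls the leakage
#' channel. Negative values (strategy scoring above random) are legitimate
#' and reported as-is; subtasks with non-positive random scores are
#' excluded with a warning.
#'
#' @param scores_strategy,scores_random Named numeric vectors of
#'   per-subtask mean scores with matching names.
#' @return List: `per_subtask` (named percent vector), `average`.
#' @export
percent_metric_decrease <- function(scores_strategy, scores_random) {
  common <- intersect(names(scores_strategy), names(scores_random))
  if (!length(common)) stop("no matching subtask keys")
  s <- scores_strategy[common]; r <- scores_random[common]
  ok <- r > 0
  if (any(!ok))
    warning("excluding subtask(s) with non-positive random score: ",
            paste(common[!ok], collapse = ", "))
  pct <- 100 * (r[ok] - s[ok]) / r[ok]
  list(per_subtask = pct, average = mean(pct))
}

#' Compare two models' scores
#'
#' Paired comparisons (same datasets/seeds for both models) use the
#' two-sided Wilcoxon signed-rank test, exact for n <= 25 and a
#' tie-corrected normal approximation beyond; independent groups use
#' Welch's unequal-variance t-test.
#'
#' @param a_scores,b_scores Numeric vectors: paired and equal-length for
#'   `"wilcoxon_signed_rank"`, two independent groups for `"welch_t"`.
#' @param mode `"wilcoxon_signed_rank"` or `"welch_t"`.
#' @return List `statistic`, `p_value`, `method`.
#' @export
compare_models <- function(a_scores, b_scores,
                           mode = c("wilcoxon_signed_rank", "welch_t")) {
  mode <- match.arg(mode)
  if (mode == "wilcoxon_signed_rank") {
    if (length(a_scores) != length(b_scores))
      stop("wilcoxon mode requires paired, equal-length score lists")
    d <- a_scores - b_scores
    if (all(d == 0))
      stop("degenerate test: all paired differences are zero")
    n <- sum(d != 0)
    ht <- suppressWarnings(
      wilcox.test(a_scores, b_scores, paired = TRUE,
                  exact = (n <= 25) && !any(duplicated(abs(d[d != 0]))),
                  correct = TRUE))
  } else {
    ht <- t.test(a_scores, b_scores, var.equal = FALSE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = mode)
}
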