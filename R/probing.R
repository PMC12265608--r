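#' Pool per-unit embeddings into one transcript vector
#'
#' Transcript-level embeddings are the arithmetic mean over per-nucleotide
#' (or per-chunk) embeddings. For chunked inputs, chunk means are
#' recombined weighted by chunk length, which equals the mean over all
#' underlying positions when chunks do not overlap.
#'
#' @param per_unit Numeric matrix, one row per unit (nucleotide or chunk).
#' @param chunk_lengths Optional integer vector of per-row weights (chunk
#'   lengths).
#' @return Numeric vector of length `ncol(per_unit)`.
#' @export
pool_embeddings <- function(per_unit, chunk_lengths = NULL) {
  per_unit <- as.matrix(per_unit)
  if (nrow(per_unit) == 0L) stop("cannot pool an empty embedding")
  if (is.null(chunk_lengths)) return(colMeans(per_unit))
  if (length(chunk_lengths) != nrow(per_unit))
    stop("one chunk length per row required")
  as.vector(crossprod(per_unit, chunk_lengths) / sum(chunk_lengths))
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integral of the PR curve: sweeping thresholds from high to
#' low scores, AP = sum over distinct thresholds of
#' `(recall step) * precision`. Ties in scores are handled by moving the
#' threshold across all tied items at once.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric vector of the same length (higher = more
#'   positive).
#' @return AP in `[0, 1]`; errors if labels are single-class.
#' @export
average_precision <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || n_pos == length(labels))
    stop("average precision undefined for single-class labels")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); n_seen <- seq_along(lab)
  last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[last_of_tie]; n_seen <- n_seen[last_of_tie]
  prec <- tp / n_seen
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

# Ridge regression with unpenalized intercept on already standardized X.
fit_ridge <- function(X, y, lambda) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  beta <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, y - ym))
  list(beta = beta, x_mean = xm, intercept = ym,
       predict = function(Xnew)
         as.vector(sweep(as.matrix(Xnew), 2L, xm) %*% beta + ym))
}

# Column standardization using train statistics only; constant columns are
# centred but left unscaled.
train_standardizer <- function(X_train) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2L, sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  function(X) sweep(sweep(as.matrix(X), 2L, mu), 2L, sdv, "/")
}

#' Fit a linear probe on frozen embeddings and score it on test
#'
#' The probe never sees test information: feature standardization uses
#' train statistics only, and the model is fit on train rows alone.
#' Regression tasks use ridge least squares scored by Pearson r on test;
#' binary tasks a ridge-penalized logistic model scored by AUPRC;
#' multilabel tasks fit one-vs-rest probes and report the unweighted mean
#' AUPRC over labels with both classes present in test (single-class test
#' labels are excluded with a warning).
#'
#' @param train,test Lists with elements `embeddings` (an
#'   [embedding_matrix()] or plain matrix with rownames) and `labels`
#'   (vector, or matrix/data frame for multilabel, rows keyed by id).
#' @param task A [task_spec()].
#' @param regularization Ridge penalty strength (default 1).
#' @param seed Integer seed (kept for provenance; fitting is
#'   deterministic).
#' @return List of class `"probe_result"`: `metric_name`, `value`, `seed`,
#'   `n_train`, `n_test`, and (regression/binary) the test `predictions` —
#'   label-free, so leakage checks can assert they ignore test labels.
#' @export
fit_and_score_probe <- function(train, test, task, regularization = 1,
                                seed = NA_integer_) {
  stopifnot(inherits(task, "task_spec"))
  Xtr <- as_embed_values(train$embeddings)
  Xte <- as_embed_values(test$embeddings)
  if (length(intersect(rownames(Xtr), rownames(Xte))))
    stop("train and test ids overlap")
  std <- train_standardizer(Xtr)
  Ztr <- std(Xtr); Zte <- std(Xte)
  ytr <- align_labels(train$labels, rownames(Xtr))
  yte <- align_labels(test$labels, rownames(Xte))

  predictions <- NULL
  if (task$kind == "regression") {
    if (sd(yte) == 0)
      stop("undefined metric: test labels are constant, Pearson r needs variance")
    fit <- fit_ridge(Ztr, as.numeric(ytr), regularization)
    pred <- fit$predict(Zte)
    if (sd(pred) == 0) value <- 0 else value <- cor(pred, as.numeric(yte))
    predictions <- setNames(pred, rownames(Zte))
    metric <- "pearson_r"
  } else if (task$kind == "binary") {
    scored <- binary_probe_auprc(Ztr, as.numeric(ytr), Zte, as.numeric(yte),
                                 regularization, return_scores = TRUE)
    value <- scored$auprc
    predictions <- setNames(scored$scores, rownames(Zte))
    metric <- "auprc"
  } else {
    Ytr <- as.matrix(ytr); Yte <- as.matrix(yte)
    vals <- numeric(0)
    for (j in seq_len(ncol(Yte))) {
      if (length(unique(Yte[, j])) < 2L) {
        warning("multilabel column ", colnames(Yte)[j] %||% j,
                " single-class in test; excluded")
        next
      }
      vals <- c(vals, binary_probe_auprc(Ztr, Ytr[, j], Zte, Yte[, j],
                                         regularization))
    }
    if (!length(vals)) stop("no multilabel column scorable in test")
    value <- mean(vals)
    metric <- "mean_auprc"
  }
  structure(list(metric_name = metric, value = value, seed = seed,
                 n_train = nrow(Ztr), n_test = nrow(Zte),
                 predictions = predictions,
                 task = task$name), class = "probe_result")
}

binary_probe_auprc <- function(Ztr, ytr, Zte, yte, lambda,
                               return_scores = FALSE) {
  if (length(unique(ytr)) < 2L)
    stop("binary probe needs both classes in train")
  fit <- glmnet::glmnet(Ztr, ytr, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  scores <- as.vector(predict(fit, Zte, type = "link"))
  ap <- average_precision(yte, scores)
  if (return_scores) list(auprc = ap, scores = scores) else ap
}

as_embed_values <- function(e) {
  if (inherits(e, "embedding_matrix")) return(e$values)
  m <- as.matrix(e)
  if (is.null(rownames(m))) stop("embeddings must carry ids as rownames")
  m
}

align_labels <- function(labels, ids) {
  if (is.data.frame(labels)) {
    if ("id" %in% names(labels)) {
      rownames(labels) <- labels$id
      labels <- labels[, setdiff(names(labels), "id"), drop = FALSE]
    }
    labels <- as.matrix(labels)
  }
  if (is.matrix(labels)) {
    if (is.null(rownames(labels))) stop("label matrix must have id rownames")
    missing <- setdiff(ids, rownames(labels))
    if (length(missing)) stop("labels missing for id ", missing[1])
    out <- labels[ids, , drop = FALSE]
    if (ncol(out) == 1L) return(setNames(out[, 1], ids))
    return(out)
  }
  if (is.null(names(labels))) stop("labels must be named by id")
  missing <- setdiff(ids, names(labels))
  if (length(missing)) stop("labels missing for id ", missing[1])
  labels[ids]
}

#' @export
print.probe_result <- function(x, ...) {
  cat("<probe_result> ", x$task, ": ", x$metric_name, " = ",
      sprintf("%.4f", x$value), " (train ", x$n_train, ", test ",
      x$n_test, ")\n", sep = "")
  invisible(x)
}

#' Run the multi-seed linear-probing protocol on one dataset
#'
#' For each seed the dataset is split, a probe is fitted per subtask on
#' the frozen embeddings, and the task metric is recorded; scores are
#' summarized as the mean and standard error across seeds — the protocol
#' under which models are compared.
#'
#' @param dataset A [labeled_dataset()].
#' @param embedder Function taking the list of transcripts and returning
#'   an [embedding_matrix()] covering all ids (e.g. a wrapper around
#'   [kmer_count_embed()]).
#' @param splitter Function `(dataset, seed) -> split_assignment`, e.g. a
#'   wrapper around [random_split()] over the dataset's transcript ids.
#' @param n_seeds Number of random splits (default 10).
#' @param seeds Optional explicit seed vector overriding `n_seeds`.
#' @param regularization Probe ridge penalty.
#' @param model_name Name recorded in the score table.
#' @return Data frame of class `"score_table"` with one row per
#'   (subtask, seed): columns `model`, `dataset`, `subtask`, `seed`,
#'   `metric`, `value`. Attribute `"summary"` holds per-subtask mean, SE
#'   and the number of successful seeds.
#' @export
run_benchmark_protocol <- function(dataset, embedder, splitter,
                                   n_seeds = 10, seeds = NULL,
                                   regularization = 1,
                                   model_name = "model") {
  stopifnot(inherits(dataset, "labeled_dataset"))
  seeds <- seeds %||% seq_len(n_seeds)
  emb <- embedder(dataset$transcripts)
  labels <- dataset$labels
  subtasks <- setdiff(names(labels), "id")
  multilabel <- dataset$task$kind == "multilabel"
  rows <- list()
  for (s in seeds) {
    split <- splitter(dataset, s)
    tr_ids <- intersect(split_ids(split, "train"), labels$id)
    te_ids <- intersect(split_ids(split, "test"), labels$id)
    lab_mat <- labels; rownames(lab_mat) <- labels$id
    if (multilabel) {
      res <- try(fit_and_score_probe(
        list(embeddings = emb$values[tr_ids, , drop = FALSE],
             labels = lab_mat[tr_ids, subtasks, drop = FALSE]),
        list(embeddings = emb$values[te_ids, , drop = FALSE],
             labels = lab_mat[te_ids, subtasks, drop = FALSE]),
        dataset$task, regularization, seed = s), silent = TRUE)
      if (!inherits(res, "try-error"))
        rows[[length(rows) + 1L]] <- data.frame(
          model = model_name, dataset = dataset$task$name,
          subtask = "all", seed = s, metric = res$metric_name,
          value = res$value)
    } else {
      for (st in subtasks) {
        res <- try(fit_and_score_probe(
          list(embeddings = emb$values[tr_ids, , drop = FALSE],
               labels = setNames(lab_mat[tr_ids, st], tr_ids)),
          list(embeddings = emb$values[te_ids, , drop = FALSE],
               labels = setNames(lab_mat[te_ids, st], te_ids)),
          dataset$task, regularization, seed = s), silent = TRUE)
        if (inherits(res, "try-error")) next
        rows[[length(rows) + 1L]] <- data.frame(
          model = model_name, dataset = dataset$task$name, subtask = st,
          seed = s, metric = res$metric_name, value = res$value)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("score_table", "data.frame")
  agg <- split(out$value, out$subtask)
  attr(out, "summary") <- data.frame(
    subtask = names(agg),
    mean = vapply(agg, mean, numeric(1)),
    se = vapply(agg, function(v)
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_, numeric(1)),
    n_seeds = lengths(agg), row.names = NULL)
  out
}
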