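test_that("pooling averages rows, weighted by chunk length when given", {
  expect_equal(pool_embeddings(rbind(c(0, 2), c(2, 0))), c(1, 1))
  expect_equal(pool_embeddings(matrix(c(3, 1, 4), 1)), c(3, 1, 4))
  m <- rbind(m1 = c(1, 0), m2 = c(4, 6))
  expect_equal(pool_embeddings(m, chunk_lengths = c(4, 2)),
               (4 * m[1, ] + 2 * m[2, ]) / 6)
  expect_error(pool_embeddings(matrix(nrow = 0, ncol = 2)), "empty")
})

test_that("average precision matches a rank-based oracle", {
  # perfectly separable: AP = 1
  expect_equal(average_precision(c(1, 1, 0, 0), c(9, 8, 2, 1)), 1)
  # worst ordering ends at prevalence-driven floor, still in (0, 1)
  expect_lt(average_precision(c(1, 0, 0, 0), c(1, 4, 3, 2)), 0.5)
  expect_error(average_precision(c(1, 1), c(1, 2)), "single-class")

  set.seed(5)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq_len(1000), n)  # tie-free
    expect_equal(average_precision(labels, scores),
                 ap_rank_oracle(labels, scores))
  }

  # ties: moving the threshold across a tied block at once
  expect_equal(average_precision(c(1, 0), c(5, 5)), 0.5)
})

test_that("a planted linear signal is recovered almost perfectly", {
  set.seed(6)
  n <- 120; d <- 10
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(paste0("s", 1:n), NULL))
  y <- setNames(X[, 1], rownames(X))
  tr <- rownames(X)[1:80]; te <- rownames(X)[81:120]
  res <- fit_and_score_probe(
    list(embeddings = X[tr, ], labels = y[tr]),
    list(embeddings = X[te, ], labels = y[te]),
    task_spec("lin", "regression"), regularization = 0.01)
  expect_gt(res$value, 0.99)
})

test_that("a separable binary toy gives AUPRC 1", {
  X <- matrix(c(rep(1, 10), rep(-1, 10)), ncol = 1,
              dimnames = list(paste0("s", 1:20), NULL))
  X <- cbind(X, 0.01 * rnorm(20))
  y <- setNames(c(rep(1, 10), rep(0, 10)), rownames(X))
  tr <- c(paste0("s", 1:5), paste0("s", 11:15))
  te <- setdiff(rownames(X), tr)
  res <- fit_and_score_probe(
    list(embeddings = X[tr, ], labels = y[tr]),
    list(embeddings = X[te, ], labels = y[te]),
    task_spec("sep", "binary"))
  expect_equal(res$value, 1)
})

test_that("probes never touch test labels or test statistics", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(paste0("s", 1:60), NULL))
  y <- setNames(X[, 2] + rnorm(60, 0, 0.1), rownames(X))
  tr <- paste0("s", 1:40); te <- paste0("s", 41:60)
  task <- task_spec("t", "regression")
  r1 <- fit_and_score_probe(list(embeddings = X[tr, ], labels = y[tr]),
                            list(embeddings = X[te, ], labels = y[te]), task)
  y_perm <- y
  y_perm[te] <- sample(y[te])
  r2 <- fit_and_score_probe(list(embeddings = X[tr, ], labels = y_perm[tr]),
                            list(embeddings = X[te, ],
                                 labels = y_perm[te]), task)
  # identical fitted probe: identical test predictions
  expect_identical(r1$predictions, r2$predictions)

  expect_error(fit_and_score_probe(
    list(embeddings = X[tr, ], labels = y[tr]),
    list(embeddings = X[te, ], labels = setNames(rep(1, 20), te)), task),
    "constant")
  expect_error(fit_and_score_probe(
    list(embeddings = X[tr, ], labels = y[tr]),
    list(embeddings = X[c(tr[1], te), ], labels = y[c(tr[1], te)]), task),
    "overlap")
})

test_that("multilabel probes average AUPRC over scorable columns", {
  set.seed(8)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(paste0("s", 1:n), NULL))
  Y <- cbind(l1 = as.numeric(X[, 1] > 0),
             l2 = as.numeric(X[, 2] > 0.2),
             l3 = rep(0, n))  # degenerate column
  rownames(Y) <- rownames(X)
  tr <- paste0("s", 1:60); te <- paste0("s", 61:80)
  expect_warning(
    res <- fit_and_score_probe(
      list(embeddings = X[tr, ], labels = Y[tr, ]),
      list(embeddings = X[te, ], labels = Y[te, ]),
      task_spec("ml", "multilabel")),
    "single-class")
  expect_true(res$value > 0.5 && res$value <= 1)
})

test_that("the protocol emits one record per subtask and seed", {
  set.seed(9)
  seqs <- setNames(vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
    character(1)), sprintf("t%02d", 1:50))
  txs <- lapply(names(seqs), function(id) transcript(id, seqs[[id]]))
  labels <- data.frame(id = names(seqs),
                       y1 = rnorm(50), y2 = rnorm(50))
  ds <- labeled_dataset(txs, labels, task_spec("toy", "regression"))
  embedder <- function(trs) kmer_count_embed(
    setNames(vapply(trs, `[[`, character(1), "sequence"),
             vapply(trs, `[[`, character(1), "id")), k = 2)
  splitter <- function(d, s) random_split(
    vapply(d$transcripts, `[[`, character(1), "id"), 0.3, s)
  tab <- run_benchmark_protocol(ds, embedder, splitter, n_seeds = 3)
  expect_equal(nrow(tab), 2 * 3)
  expect_setequal(unique(tab$subtask), c("y1", "y2"))
  smry <- attr(tab, "summary")
  expect_equal(smry$n_seeds, c(3L, 3L))

  tab2 <- run_benchmark_protocol(ds, embedder, splitter, n_seeds = 3)
  expect_equal(tab$value, tab2$value)
})

test_that("a planted motif is linearly decodable under random splits", {
  set.seed(10)
  n <- 80
  base <- vapply(1:n, function(i)
    paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = ""),
    character(1))
  pos <- seq_len(n) <= n / 2
  base[pos] <- vapply(base[pos], function(s) {
    at <- sample(1:70, 1)
    paste0(substr(s, 1, at - 1), "GCGC", substr(s, at + 4, 80))
  }, character(1))
  names(base) <- sprintf("m%02d", 1:n)
  y <- setNames(as.numeric(vapply(base, function(s)
    txbench:::count_motif(s, "GCGC") > 0, logical(1))), names(base))
  emb <- kmer_count_embed(base, k = 4)
  task <- task_spec("motif", "binary", locality = "local")
  vals <- vapply(1:3, function(s) {
    sp <- random_split(names(base), 0.25, s)
    tr <- split_ids(sp, "train"); te <- split_ids(sp, "test")
    fit_and_score_probe(
      list(embeddings = emb$values[tr, ], labels = y[tr]),
      list(embeddings = emb$values[te, ], labels = y[te]), task)$value
  }, numeric(1))
  expect_gt(mean(vals), 0.9)
})
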