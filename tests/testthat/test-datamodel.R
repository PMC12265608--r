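test_that("FASTA records parse with header metadata and normalization", {
  f <- write_temp_fasta(c(">tx1 gene=G1 chrom=chr1", "ACGT"))
  tx <- read_fasta(f)
  expect_length(tx, 1)
  expect_equal(tx[[1]]$id, "tx1")
  expect_equal(tx[[1]]$gene_id, "G1")
  expect_equal(tx[[1]]$chromosome, "chr1")
  expect_equal(tx[[1]]$sequence, "ACGT")

  # lower case and U are normalized onto the canonical DNA alphabet
  f2 <- write_temp_fasta(c(">tx2", "acgu"))
  expect_equal(read_fasta(f2)[[1]]$sequence, "ACGT")

  # empty file is an empty transcript list
  f3 <- tempfile(fileext = ".fasta")
  file.create(f3)
  expect_identical(read_fasta(f3), list())
})

test_that("FASTA reader rejects malformed input and duplicate ids", {
  bad <- write_temp_fasta(c("ACGT", ">tx1", "ACGT"))
  expect_error(read_fasta(bad), "line 1")
  dup <- write_temp_fasta(c(">tx1", "ACGT", ">tx1", "GGGG"))
  expect_error(read_fasta(dup), "duplicate")
})

test_that("FASTA round-trip preserves full transcript records", {
  set.seed(42)
  txs <- lapply(1:8, function(i) random_transcript(paste0("t", i)))
  f <- tempfile(fileext = ".fasta")
  write_fasta(txs, f)
  back <- read_fasta(f)
  expect_equal(back, txs)
})

test_that("transcript invariants are enforced", {
  expect_error(transcript("x", "ACGT", exon_starts = c(1L)), "must be 0")
  expect_error(transcript("x", "ACGT", exon_starts = c(0L, 4L)),
               "lie in")
  expect_error(transcript("x", "ACGT", exon_starts = c(0L, 2L, 2L)),
               "strictly increasing")
  expect_error(transcript("x", "ACGTAC", cds = c(0, 4)), "multiple of 3")
  expect_error(transcript("x", "ACGTAC", cds = c(3, 3)), "start < end")
  expect_error(transcript("x", "ACXT"), "invalid character")
})

test_that("task specs tie metric to label kind", {
  expect_equal(task_spec("t", "regression")$metric, "pearson_r")
  expect_equal(task_spec("t", "binary")$metric, "auprc")
  expect_equal(task_spec("t", "multilabel")$metric, "mean_auprc")
  expect_error(task_spec("t", "regression", metric = "auprc"),
               "incompatible")
})

test_that("label tables parse, coerce and validate", {
  task <- task_spec("y", "regression")
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\ty", "tx1\t0.5"), f)
  tab <- read_label_table(f, task)
  expect_equal(tab$y, 0.5)
  expect_equal(tab$id, "tx1")

  # header-only file gives an empty table with the right columns
  writeLines("id\ty", f)
  empty <- read_label_table(f, task)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("id", "y"))

  # multilabel values outside {0,1} are rejected
  writeLines(c("id\ta\tb", "tx1\t1\t2"), f)
  expect_error(read_label_table(f, task_spec("m", "multilabel")), "0/1")

  # non-numeric regression labels name the offending row
  writeLines(c("id\ty", "tx1\t0.5", "tx2\thigh"), f)
  expect_error(read_label_table(f, task), "row 2")

  writeLines(c("name\ty", "tx1\t0.5"), f)
  expect_error(read_label_table(f, task), "first column must be 'id'")
})

test_that("labeled_dataset validates id consistency", {
  txs <- list(transcript("a", "ACGT"), transcript("b", "GGCC"))
  task <- task_spec("y", "regression")
  ok <- labeled_dataset(txs, data.frame(id = c("a", "b"), y = c(1, 2)), task)
  expect_s3_class(ok, "labeled_dataset")
  expect_error(
    labeled_dataset(txs, data.frame(id = c("a", "z"), y = c(1, 2)), task),
    "absent")
  expect_error(
    labeled_dataset(txs, data.frame(id = c("a", "a"), y = c(1, 2)), task),
    "duplicate")
})

test_that("six-track encoding marks bases, splice sites and codon starts", {
  m <- six_track_encode(transcript("t", "ATG", cds = c(0, 3)))
  expect_equal(unname(m["splice", ]), c(1, 0, 0))
  expect_equal(unname(m["codon", ]), c(1, 0, 0))

  m2 <- six_track_encode(transcript("t", "ATGATG", cds = c(0, 6)))
  expect_equal(unname(m2["codon", ]), c(1, 0, 0, 1, 0, 0))

  # N columns are all-zero in the one-hot rows and the codon track
  m3 <- six_track_encode(transcript("t", "NN"))
  expect_equal(sum(m3[c(1:4, 6), ]), 0)

  # property: column count = length; every non-N column one-hot
  set.seed(7)
  for (i in 1:10) {
    tx <- random_transcript(paste0("p", i))
    enc <- six_track_encode(tx)
    expect_equal(ncol(enc), nchar(tx$sequence))
    expect_true(all(colSums(enc[1:4, , drop = FALSE]) == 1))
    expect_equal(sum(enc["splice", ]), length(tx$exon_starts))
    if (!is.null(tx$cds))
      expect_equal(sum(enc["codon", ]), (tx$cds[2] - tx$cds[1]) / 3)
  }
})

test_that("chunking respects length bounds and reconstructs the sequence", {
  s10 <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
               collapse = "")
  expect_equal(nchar(chunk_sequence(s10, 4, 0)), c(4, 4, 2))
  expect_equal(chunk_sequence("ACG", 8, 0), "ACG",
               ignore_attr = TRUE)
  expect_equal(attr(chunk_sequence(s10, 4, 2), "starts"), c(0L, 2L, 4L, 6L, 8L))
  expect_error(chunk_sequence(s10, 4, 4), "smaller than max_len")

  # overlap = 0 partitions; overlap > 0 reconstructs after trimming
  set.seed(11)
  for (i in 1:20) {
    L <- sample(5:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
               collapse = "")
    ml <- sample(2:12, 1)
    ov <- sample(0:(ml - 1), 1)
    ch <- chunk_sequence(s, ml, ov)
    expect_true(all(nchar(ch) <= ml))
    trimmed <- c(ch[1], substring(ch[-1], ov + 1))
    expect_equal(paste(trimmed, collapse = ""), s)
  }
})
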