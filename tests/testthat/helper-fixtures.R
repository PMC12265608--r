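# Fixture builders shared by the suite; everything is generated in code.

write_temp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

random_transcript <- function(id, len = NULL, seed_chars = c("A", "C", "G", "T")) {
  len <- len %||% sample(30:90, 1)
  n_exons <- sample(1:3, 1)
  exon_starts <- sort(c(0L, sample(seq_len(len - 1L),
                                   n_exons - 1L)))
  cds <- NULL
  if (runif(1) < 0.7 && len >= 12) {
    start <- sample(0:(len - 9L), 1)
    n_codons <- sample(seq_len((len - start) %/% 3L), 1)
    cds <- c(start, start + 3L * n_codons)
  }
  transcript(id, paste(sample(seed_chars, len, replace = TRUE),
                       collapse = ""),
             gene_id = paste0("g_", id),
             chromosome = sample(paste0("chr", 1:4), 1),
             exon_starts = exon_starts, cds = cds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A family corpus with a motif planted in the ancestors of half the
# families: the leakage-study fixture. Labels are motif presence measured
# on the realized (mutated) sequences.
motif_family_corpus <- function(n_families = 30, family_size = 6,
                                seq_len = 150, motif = "ACGTG",
                                mut = 0.15, seed = 1) {
  set.seed(seed)
  seqs <- character(0); fam_of <- integer(0)
  positive_family <- rep(c(TRUE, FALSE), length.out = n_families)
  for (f in seq_len(n_families)) {
    anc <- sample(c("A", "C", "G", "T"), seq_len, replace = TRUE)
    if (positive_family[f]) {
      pos <- sample(seq_len(seq_len - nchar(motif)), 1)
      anc[pos:(pos + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    }
    for (m in seq_len(family_size)) {
      s <- anc
      hit <- runif(seq_len) < mut
      if (any(hit))
        s[hit] <- vapply(s[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      seqs <- c(seqs, paste(s, collapse = ""))
      fam_of <- c(fam_of, f)
    }
  }
  names(seqs) <- sprintf("s%03d", seq_along(seqs))
  labels <- as.numeric(vapply(seqs, function(s)
    txbench:::count_motif(s, motif) > 0, logical(1)))
  list(sequences = seqs, labels = setNames(labels, names(seqs)),
       family = setNames(fam_of, names(seqs)))
}

# Mean AUPRC of a k-mer-embedding probe on a labelled corpus under a given
# splitter, across seeds.
probe_auprc_over_seeds <- function(corpus, splitter_fun, seeds, k = 5) {
  emb <- kmer_count_embed(corpus$sequences, k = k)
  task <- task_spec("motif", "binary", locality = "local")
  vapply(seeds, function(s) {
    sp <- splitter_fun(s)
    tr <- split_ids(sp, "train"); te <- split_ids(sp, "test")
    res <- try(fit_and_score_probe(
      list(embeddings = emb$values[tr, , drop = FALSE],
           labels = corpus$labels[tr]),
      list(embeddings = emb$values[te, , drop = FALSE],
           labels = corpus$labels[te]),
      task), silent = TRUE)
    if (inherits(res, "try-error")) NA_real_ else res$value
  }, numeric(1))
}
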