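test_that("Markov generator honours degenerate chains and determinism", {
  spec <- region_grammar_spec("allA", order = 1,
                              initial_probs = c(1, 0, 0, 0),
                              transition_probs = diag(4))
  out <- simulate_markov_region(spec, 5, c(10, 10), seed = 3)
  expect_true(all(out == strrep("A", 10)))

  u <- region_grammar_spec("uniform")
  expect_identical(simulate_markov_region(u, 20, c(5, 30), 9),
                   simulate_markov_region(u, 20, c(5, 30), 9))
  expect_error(region_grammar_spec("bad", order = 1,
                                   transition_probs = matrix(1, 4, 4)),
               "sum to 1")
})

test_that("order-0 empirical base frequencies converge to the spec", {
  u <- region_grammar_spec("uniform")
  seqs <- simulate_markov_region(u, 1500, c(100, 100), seed = 5)
  counts <- txbench:::count_kmers_one(paste(seqs, collapse = ""), 1)
  freqs <- counts / sum(counts)
  expect_true(all(abs(freqs - 0.25) < 0.01))
})

test_that("order-1 empirical transition frequencies match the matrix", {
  P <- matrix(c(.7, .1, .1, .1,
                .1, .7, .1, .1,
                .1, .1, .7, .1,
                .1, .1, .1, .7), 4, 4, byrow = TRUE)
  spec <- region_grammar_spec("sticky", order = 1,
                              transition_probs = P)
  seqs <- simulate_markov_region(spec, 400, c(250, 250), seed = 6)
  big <- paste(seqs, collapse = "|")  # separator breaks cross-seq pairs
  from <- substring(big, 1:(nchar(big) - 1), 1:(nchar(big) - 1))
  to <- substring(big, 2:nchar(big), 2:nchar(big))
  keep <- from %in% c("A", "C", "G", "T") & to %in% c("A", "C", "G", "T")
  tab <- table(from[keep], to[keep])
  emp <- tab / rowSums(tab)
  n_per_row <- rowSums(tab)
  for (i in 1:4) for (j in 1:4) {
    se <- sqrt(P[i, j] * (1 - P[i, j]) / n_per_row[i])
    expect_lt(abs(emp[i, j] - P[i, j]), 3 * se + 1e-3)
  }
})

test_that("codon generator follows the usage table", {
  usage <- setNames(rep(0, 64), all_kmers(3))
  usage["ATG"] <- 1
  expect_equal(simulate_cds_region(usage, 3, 4, seed = 1),
               rep(strrep("ATG", 4), 3))
  expect_true(all(nchar(simulate_cds_region(rep(1 / 64, 64), 5, 2, 1)) == 6))
  expect_error(simulate_cds_region(rep(0.5, 64), 1, 1, 1), "sum to 1")

  # uniform usage: per-codon frequency near 1/64
  seqs <- simulate_cds_region(rep(1 / 64, 64), 200, 100, seed = 2)
  toks <- unlist(lapply(seqs, tokenize_blocks, k = 3))
  freqs <- table(factor(toks, levels = all_kmers(3))) / length(toks)
  se <- sqrt((1 / 64) * (63 / 64) / length(toks))
  expect_true(all(abs(freqs - 1 / 64) < 4 * se))
})

test_that("paralog families realize the stated mutation model", {
  # zero mutation: all members identical, and pair counting is exact
  fam0 <- simulate_paralog_families(3, 2, 40, target_identity = 1, seed = 1)
  expect_equal(nrow(fam0$edges), 3)
  expect_true(all(fam0$edges$identity == 1))

  # mu = 0.1 per member: two members of one family match per site with
  # probability (1-mu)^2 + mu^2/3 (exact counting oracle)
  mu <- 0.1
  fam <- simulate_paralog_families(4, 3, 2000, target_identity = 1 - mu,
                                   seed = 2)
  expected <- (1 - mu)^2 + mu^2 / 3
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_true(all(abs(fam$edges$identity - expected) < 4 * se))
  expect_equal(nrow(fam$edges), 4 * choose(3, 2))
  expect_error(simulate_paralog_families(2, 2, 10, 0, 1), "target_identity")
})

test_that("motif labels follow presence / linear-count rules", {
  bin <- task_spec("b", "binary", locality = "local")
  reg <- task_spec("r", "regression", locality = "local")
  lab <- simulate_motif_labels(c(s1 = "AAACGTAA", s2 = "AAAA"), "ACGT", bin)
  expect_equal(lab$label, c(1, 0))
  lab2 <- simulate_motif_labels(c(x = "ACGTACGTACGT"), "ACGT", reg,
                                effect = 2, noise_sd = 0)
  expect_equal(lab2$label, 6)  # 3 occurrences x effect 2
  expect_error(simulate_motif_labels(c(a = "ACGT"), "", bin), "non-empty")
})

test_that("MPRA generator balances cells and guarantees uAUG structure", {
  model <- mpra_label_model(beta0 = 1, beta_kozak = 2, beta_uaug = 1,
                            gamma = 0, noise_sd = 0)
  ds <- simulate_mpra_utrs(8, model, utr_len = 40, seed = 4)
  ann <- ds$annotations
  cells <- table(ann$kozak, ann$has_uaug)
  expect_true(all(cells == 8))

  utr_of <- function(t) substr(t$sequence, 1, t$cds[1])
  for (t in ds$transcripts) {
    ua <- ann$has_uaug[ann$id == t$id]
    n_atg <- txbench:::count_motif(utr_of(t), "ATG")
    if (ua) expect_gte(n_atg, 1) else expect_equal(n_atg, 0)
    # Kozak call recoverable from the sequence itself
    got <- annotate_utr(t$sequence, t$cds[1])
    expect_equal(got$kozak, ann$kozak[ann$id == t$id])
    expect_equal(got$has_uaug, ua)
  }

  # noiseless binary-mode labels plug into the formula exactly
  y <- setNames(ds$labels$mrl, ds$labels$id)
  expect_true(all(y[ann$id[ann$kozak == "strong" & !ann$has_uaug]] == 3))
  expect_true(all(y[ann$id[ann$kozak == "weak" & ann$has_uaug]] == 0))

  # noise variance matches the model (residuals after the known formula)
  noisy <- simulate_mpra_utrs(150, mpra_label_model(noise_sd = 0.3),
                              utr_len = 30, seed = 5)
  a2 <- noisy$annotations
  mu <- with(a2, 5 + 2 * (kozak == "strong") - 2 * has_uaug)
  resid <- setNames(noisy$labels$mrl, noisy$labels$id)[a2$id] - mu
  expect_lt(abs(mean(resid)), 0.05)
  expect_lt(abs(sd(resid) - 0.3), 0.05)
})

test_that("k-mer embedding counts overlapping words in fixed order", {
  e1 <- kmer_count_embed(c(a = "AAAA"), k = 1, normalize = FALSE)
  expect_equal(unname(e1$values[1, ]), c(4, 0, 0, 0))
  e2 <- kmer_count_embed(c(a = "ACGT"), k = 2, normalize = FALSE)
  expect_equal(e2$values[1, c("AC", "CG", "GT")], c(AC = 1, CG = 1, GT = 1))
  expect_equal(sum(e2$values), 3)
  e3 <- kmer_count_embed(c(a = "AAAA"), k = 1, normalize = TRUE)
  expect_equal(unname(e3$values[1, "A"]), 1)
  expect_error(kmer_count_embed(c(tiny = "AC"), k = 3), "tiny")
  expect_equal(colnames(e2$values), all_kmers(2))
})
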