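test_that("random split hits the requested size deterministically", {
  ids <- paste0("t", 1:10)
  sp <- random_split(ids, 0.2, seed = 1)
  expect_equal(sum(sp$assignment == "test"), 2)
  expect_equal(sum(sp$assignment == "train"), 8)
  expect_identical(random_split(ids, 0.2, 7)$assignment,
                   random_split(ids, 0.2, 7)$assignment)
  expect_error(random_split(ids, 0, 1), "test_frac")
  expect_error(random_split("one", 0.5, 1), "at least 2")
})

test_that("chromosome split holds out whole chromosomes", {
  txs <- c(lapply(1:4, function(i)
    transcript(paste0("a", i), "ACGTACGT", chromosome = "chr1")),
    lapply(1:3, function(i)
      transcript(paste0("b", i), "ACGTACGT", chromosome = "chr2")))
  sp <- chromosome_split(txs, "chr2")
  expect_setequal(split_ids(sp, "test"), paste0("b", 1:3))
  expect_setequal(split_ids(sp, "train"), paste0("a", 1:4))
  expect_warning(chromosome_split(txs, "chrX"), "test side empty")
  expect_error(chromosome_split(txs, c("chr1", "chr2")), "train side empty")
  expect_error(chromosome_split(txs, character(0)), "non-empty")
})

test_that("k-mer cluster split never divides a cluster", {
  # two composition-distinct sets must each stay whole
  seqs <- c(setNames(rep(strrep("A", 30), 6), paste0("a", 1:6)),
            setNames(rep(strrep("C", 30), 6), paste0("c", 1:6)))
  sp <- kmer_cluster_split(seqs, k = 1, n_clusters = 2, test_frac = 0.5,
                           seed = 1)
  side_a <- unique(sp$assignment[paste0("a", 1:6)])
  side_c <- unique(sp$assignment[paste0("c", 1:6)])
  expect_length(side_a, 1)
  expect_length(side_c, 1)
  expect_false(side_a == side_c)

  # general case: no cluster straddles the split; reproducible
  set.seed(2)
  rseqs <- setNames(vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1)), paste0("r", 1:40))
  sp2 <- kmer_cluster_split(rseqs, k = 2, n_clusters = 8, test_frac = 0.25,
                            seed = 3)
  cl <- attr(sp2, "clusters")
  for (g in split(names(cl), cl))
    expect_length(unique(sp2$assignment[g]), 1)
  expect_identical(sp2$assignment,
                   kmer_cluster_split(rseqs, k = 2, n_clusters = 8,
                                      test_frac = 0.25, seed = 3)$assignment)
  expect_error(kmer_cluster_split(rseqs, n_clusters = 100), "exceeds")

  # achieved fraction within the greedy bound
  sizes <- table(cl)
  achieved <- mean(sp2$assignment == "test")
  expect_lte(abs(achieved - 0.25), max(sizes) / 40 + 1 / 40)
})

test_that("positional identity counts matches", {
  expect_equal(pairwise_identity("ACGT", "ACGT"), 1)
  expect_equal(pairwise_identity("ACGT", "ACGA"), 0.75)
  expect_error(pairwise_identity("ACGT", "ACG"), "equal lengths")
  expect_error(pairwise_identity("", ""), "non-empty")
})

test_that("transitive groups equal brute-force reachability", {
  edges <- paralog_edges(data.frame(gene_a = c("A", "B", "D"),
                                    gene_b = c("B", "C", "E")))
  groups <- transitive_groups(edges, LETTERS[1:6])
  expect_equal(groups, list(c("A", "B", "C"), c("D", "E"), "F"))

  none <- transitive_groups(paralog_edges(
    data.frame(gene_a = character(0), gene_b = character(0))), c("x", "y"))
  expect_equal(none, list("x", "y"))

  expect_error(transitive_groups(
    paralog_edges(data.frame(gene_a = "A", gene_b = "Z")), c("A", "B")),
    "unknown gene")

  # randomized graphs against the BFS oracle
  set.seed(4)
  for (rep in 1:40) {
    n <- sample(3:12, 1)
    genes <- paste0("g", seq_len(n))
    n_e <- sample(0:(2 * n), 1)
    e <- if (n_e == 0) data.frame(gene_a = character(0),
                                  gene_b = character(0))
    else {
      pairs <- t(replicate(n_e, sample(genes, 2)))
      data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2])
    }
    expect_equal(transitive_groups(paralog_edges(e), genes),
                 reachability_groups(e, genes))
  }
})

test_that("homology split keeps paralog groups intact", {
  fam <- simulate_paralog_families(8, 3, 60, target_identity = 0.9, seed = 5)
  sp <- homology_split(fam$transcripts, fam$edges, identity_threshold = 0.35,
                       test_frac = 0.25, seed = 1)
  # no surviving edge crosses the split (exhaustive)
  for (i in seq_len(nrow(fam$edges)))
    expect_equal(sp$assignment[[fam$edges$gene_a[i]]],
                 sp$assignment[[fam$edges$gene_b[i]]])
  expect_equal(leakage_report(sp, fam$edges)$crossing_pairs, 0)

  # low-identity edges are discarded before grouping
  txs <- list(transcript("p", "ACGTACGTAC"), transcript("q", "TTTTACGTAC"),
              transcript("r", "GGGGGGGGGG"))
  weak_edge <- paralog_edges(data.frame(gene_a = "p", gene_b = "q",
                                        identity = 0.30))
  sp2 <- homology_split(txs, weak_edge, identity_threshold = 0.35,
                        test_frac = 0.34, seed = 2)
  expect_equal(length(attr(sp2, "groups")), 3)  # all singletons
  strong_edge <- paralog_edges(data.frame(gene_a = "p", gene_b = "q",
                                          identity = 0.60))
  sp3 <- homology_split(txs, strong_edge, identity_threshold = 0.35,
                        test_frac = 0.34, seed = 2)
  expect_equal(length(attr(sp3, "groups")), 2)
  expect_equal(sp3$assignment[["p"]], sp3$assignment[["q"]])

  # a single all-spanning group cannot be split
  chain <- paralog_edges(data.frame(gene_a = c("p", "q"),
                                    gene_b = c("q", "r"),
                                    identity = c(0.9, 0.9)))
  expect_error(homology_split(txs, chain, test_frac = 0.3, seed = 1),
               "un-splittable")
})

test_that("random splits leak paralog pairs that homology splits forbid", {
  fam <- simulate_paralog_families(1, 2, 30, target_identity = 0.95,
                                  seed = 6)
  ids <- vapply(fam$transcripts, `[[`, character(1), "id")
  crossed <- vapply(1:20, function(s) {
    sp <- random_split(ids, 0.5, seed = s)
    leakage_report(sp, fam$edges)$crossing_pairs
  }, integer(1))
  expect_gt(sum(crossed), 0)

  empty <- paralog_edges(data.frame(gene_a = character(0),
                                    gene_b = character(0)))
  rep0 <- leakage_report(random_split(ids, 0.5, 1), empty)
  expect_equal(rep0$crossing_pairs, 0)
  expect_equal(rep0$n_edges, 0)
})

test_that("leakage report measures k-mer overlap between sides", {
  seqs <- c(tr1 = "ACGTACGTACGT", tr2 = "ACGTACGTTTTT", te1 = "ACGTACGAAAAA")
  sp <- split_assignment(c(tr1 = "train", tr2 = "train", te1 = "test"),
                         "manual")
  empty <- paralog_edges(data.frame(gene_a = character(0),
                                    gene_b = character(0)))
  rep <- leakage_report(sp, empty, sequences = seqs, k = 4, motif = "ACGT")
  expect_true(rep$test_kmer_overlap > 0 && rep$test_kmer_overlap <= 1)
  expect_true(rep$motif_in_train)
})
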