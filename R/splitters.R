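#' Random train/test split
#'
#' The naive baseline every biologically-aware strategy is compared
#' against. Ignores all structure among records, so homologous or
#' motif-sharing sequences routinely land on both sides.
#'
#' @param ids Character vector of record ids (length >= 2).
#' @param test_frac Fraction of records assigned to test, in (0, 1).
#' @param seed Integer seed.
#' @return A [split_assignment()].
#' @export
random_split <- function(ids, test_frac, seed) {
  if (length(ids) < 2L) stop("need at least 2 ids to split")
  if (!is_fraction(test_frac)) stop("test_frac must be in (0, 1)")
  set.seed(seed)
  n_test <- round(test_frac * length(ids))
  n_test <- max(1L, min(length(ids) - 1L, n_test))
  test <- sample(ids, n_test)
  assign <- setNames(ifelse(ids %in% test, "test", "train"), ids)
  split_assignment(assign, "random", seed, list(test_frac = test_frac))
}

#' Chromosomal holdout split
#'
#' Every transcript whose chromosome is in `held_out` goes to test, all
#' others to train. The commonest genomics holdout; coarse, and known to
#' leak through inter-chromosomal homology.
#'
#' @param records List of [transcript()] objects.
#' @param held_out Non-empty character vector of chromosome names.
#' @return A [split_assignment()]. Warns if no record lies on a held-out
#'   chromosome; errors if *all* do (empty train side).
#' @export
chromosome_split <- function(records, held_out) {
  if (!length(held_out)) stop("held_out must be non-empty")
  ids <- vapply(records, `[[`, character(1), "id")
  chrom <- vapply(records, `[[`, character(1), "chromosome")
  in_test <- chrom %in% held_out
  if (all(in_test)) stop("held_out covers every record: train side empty")
  if (!any(in_test))
    warning("no record on held-out chromosome(s): test side empty")
  assign <- setNames(ifelse(in_test, "test", "train"), ids)
  split_assignment(assign, "chromosome", NA_integer_,
                   list(held_out = held_out))
}

#' K-mer-cluster split
#'
#' Sequences are represented by row-normalized overlapping k-mer frequency
#' vectors and clustered with k-means; whole clusters are then assigned to
#' the test side (largest first, ties in seeded random order) until the
#' requested fraction is reached, the remainder to train. Because clusters
#' are never divided, sequences sharing short motif vocabulary cannot
#' straddle the split — the leakage channel this strategy closes.
#'
#' @param sequences Named character vector (names are ids).
#' @param k Word length of the frequency vectors (default 5, mid-range of
#'   typical RBP motif lengths).
#' @param n_clusters Number of k-means clusters (>= 2, <= number of
#'   sequences); defaults to `max(10, n/50)` capped at `n`.
#' @param test_frac Target test fraction.
#' @param seed Integer seed (fixes both k-means initialization and
#'   tie-breaking).
#' @return A [split_assignment()]; cluster membership is attached as
#'   attribute `"clusters"` (named integer vector).
#' @export
kmer_cluster_split <- function(sequences, k = 5, n_clusters = NULL,
                               test_frac = 0.2, seed = 1) {
  if (!is_fraction(test_frac)) stop("test_frac must be in (0, 1)")
  n <- length(sequences)
  if (is.null(names(sequences))) stop("sequences must be named by id")
  n_clusters <- n_clusters %||% min(n, max(10L, round(n / 50)))
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (n_clusters > n) stop("n_clusters exceeds number of sequences")
  emb <- kmer_count_embed(sequences, k, normalize = TRUE)
  set.seed(seed)
  km <- kmeans(emb$values, centers = n_clusters, nstart = 5L,
               iter.max = 50L)
  clusters <- setNames(km$cluster, names(sequences))
  groups <- split(names(sequences), clusters)
  assign <- assign_groups_greedy(groups, test_frac, seed, n)
  out <- split_assignment(assign, "kmer_cluster", seed,
                          list(k = k, n_clusters = n_clusters,
                               test_frac = test_frac))
  attr(out, "clusters") <- clusters
  out
}

# Greedy largest-first fill of the test side: groups ordered by decreasing
# size (ties shuffled under seed), moved to test until its size first
# reaches round(test_frac * n). Deviation from the target is bounded by the
# largest group size.
assign_groups_greedy <- function(groups, test_frac, seed, n_total) {
  sizes <- lengths(groups)
  set.seed(derive_seed(seed, "group_assign"))
  ord <- order(-sizes, sample.int(length(groups)))
  target <- max(1L, round(test_frac * n_total))
  test_ids <- character(0)
  for (g in ord) {
    if (length(test_ids) >= target) break
    test_ids <- c(test_ids, groups[[g]])
  }
  all_ids <- unlist(groups, use.names = FALSE)
  if (length(test_ids) == length(all_ids))
    stop("un-splittable: a single group spans all records")
  setNames(ifelse(all_ids %in% test_ids, "test", "train"), all_ids)
}

#' Positional sequence identity
#'
#' Fraction of matching positions between two equal-length sequences.
#' Alignment-based identity for unequal lengths is out of scope: externally
#' curated paralog tables carry their own identity column.
#'
#' @param a,b Non-empty sequences of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  if (nchar(a) != nchar(b))
    stop("positional identity requires equal lengths (", nchar(a), " vs ",
         nchar(b), ")")
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

#' Transitive paralog groups
#'
#' Connected components of the paralogy graph: genes linked directly or
#' through chains of paralog edges form one group, so a split that keeps
#' groups intact can never place two (transitively) related genes on
#' opposite sides. Genes with no edges are singleton groups.
#'
#' @param edges A [paralog_edges()] table (or data frame with `gene_a`,
#'   `gene_b`).
#' @param all_genes Character vector of every gene to group.
#' @return List of character vectors (sorted within and between groups for
#'   determinism).
#' @export
transitive_groups <- function(edges, all_genes) {
  all_genes <- unique(as.character(all_genes))
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), all_genes)
    if (length(unknown))
      stop("edge names unknown gene(s): ", paste(head(unknown, 5),
                                                 collapse = ", "))
    g <- igraph::graph_from_data_frame(
      edges[, c("gene_a", "gene_b")], directed = FALSE,
      vertices = data.frame(name = all_genes))
    comp <- igraph::components(g)$membership
  } else {
    comp <- setNames(seq_along(all_genes), all_genes)
  }
  groups <- split(names(comp), comp)
  groups <- lapply(groups, function(g) sort(unname(g)))
  names(groups) <- NULL
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

#' Homology-based split
#'
#' The most stringent leakage guard: paralog edges below the identity
#' threshold are discarded as low-confidence, transitive gene groups are
#' built from the survivors, and whole groups are assigned to train or
#' test (largest-first greedy fill, as in [kmer_cluster_split()]). All
#' transcripts of a gene move with their gene.
#'
#' @param records List of [transcript()] objects.
#' @param edges A [paralog_edges()] table; rows without an `identity`
#'   column (or with `NA` identity) are kept unconditionally.
#' @param identity_threshold Minimum identity for an edge to count
#'   (default 0.35).
#' @param test_frac Target test fraction.
#' @param seed Integer seed.
#' @return A [split_assignment()] over transcript ids; the gene groups
#'   used are attached as attribute `"groups"`.
#' @export
homology_split <- function(records, edges, identity_threshold = 0.35,
                           test_frac = 0.2, seed = 1) {
  if (!is_fraction(test_frac)) stop("test_frac must be in (0, 1)")
  ids <- vapply(records, `[[`, character(1), "id")
  genes <- vapply(records, `[[`, character(1), "gene_id")
  kept <- edges
  if (nrow(edges) && "identity" %in% names(edges)) {
    drop <- !is.na(edges$identity) & edges$identity < identity_threshold
    kept <- edges[!drop, , drop = FALSE]
  }
  groups <- transitive_groups(kept, unique(genes))
  # expand gene groups to transcript-id groups
  by_gene <- split(ids, genes)
  id_groups <- lapply(groups, function(g)
    unlist(by_gene[g], use.names = FALSE))
  assign <- assign_groups_greedy(id_groups, test_frac, seed,
                                 n_total = length(ids))
  out <- split_assignment(assign[ids], "homology", seed,
                          list(identity_threshold = identity_threshold,
                               test_frac = test_frac))
  attr(out, "groups") <- groups
  out
}

#' Leakage diagnostics for a split
#'
#' Counts paralog pairs whose two genes sit on opposite sides of the
#' split, and (optionally) the fraction of distinct test-side k-mers also
#' present on the train side, or the train-side presence of one named
#' motif — the redundancy channels through which a random split lets
#' models score without generalizing.
#'
#' @param split A [split_assignment()]; ids must be gene ids or be mapped
#'   to genes via `gene_map`.
#' @param edges A [paralog_edges()] table (may be empty).
#' @param sequences Optional named character vector (ids matching the
#'   split) enabling the k-mer overlap diagnostic.
#' @param k Word length for the k-mer diagnostic (default 5).
#' @param motif Optional single motif to look up on the train side.
#' @param gene_map Optional named vector id -> gene (defaults to identity).
#' @return List of class `"leakage_report"` with `crossing_pairs`,
#'   `n_edges`, and when sequences are given `test_kmer_overlap` (fraction)
#'   and `motif_in_train` (logical, when `motif` given).
#' @export
leakage_report <- function(split, edges, sequences = NULL, k = 5,
                           motif = NULL, gene_map = NULL) {
  stopifnot(inherits(split, "split_assignment"))
  side_of <- split$assignment
  if (!is.null(gene_map)) {
    gene_side <- tapply(side_of, gene_map[names(side_of)], function(s)
      if (length(unique(s)) == 1L) s[1] else "mixed")
    side_of <- setNames(as.character(gene_side), names(gene_side))
  }
  crossing <- 0L
  if (nrow(edges)) {
    sa <- side_of[edges$gene_a]; sb <- side_of[edges$gene_b]
    known <- !is.na(sa) & !is.na(sb)
    crossing <- sum(known & (sa != sb | sa == "mixed"))
  }
  rep <- list(crossing_pairs = as.integer(crossing),
              n_edges = nrow(edges))
  if (!is.null(sequences)) {
    tr <- sequences[intersect(names(sequences), split_ids(split, "train"))]
    te <- sequences[intersect(names(sequences), split_ids(split, "test"))]
    if (length(tr) && length(te)) {
      km_tr <- names(which(colSums(kmer_count_embed(tr, k,
        normalize = FALSE)$values) > 0))
      km_te <- names(which(colSums(kmer_count_embed(te, k,
        normalize = FALSE)$values) > 0))
      rep$test_kmer_overlap <- if (length(km_te))
        mean(km_te %in% km_tr) else NA_real_
      if (!is.null(motif))
        rep$motif_in_train <- any(vapply(tr, count_motif, integer(1),
                                         motif = motif) > 0)
    }
  }
  structure(rep, class = "leakage_report")
}

#' @export
print.leakage_report <- function(x, ...) {
  cat("<leakage_report> ", x$crossing_pairs, "/", x$n_edges,
      " paralog pairs cross the split\n", sep = "")
  if (!is.null(x$test_kmer_overlap))
    cat("  test k-mers also in train: ",
        sprintf("%.1f%%", 100 * x$test_kmer_overlap), "\n", sep = "")
  invisible(x)
}
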