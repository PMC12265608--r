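# Independent oracles used across the suite. Each deliberately avoids the
# package's own algorithmic path.

# Minimal expected prefix-code length for a set of token weights, by
# exhaustive recursion over all binary tree shapes (memoized on the token
# subset). C({l}) = 0; C(S) = w(S) + min over proper subsets A of
# C(A) + C(S \ A).
optimal_code_cost <- function(weights) {
  n <- length(weights)
  stopifnot(n >= 2, n <= 12)
  memo <- new.env(parent = emptyenv())
  subset_weight <- vapply(seq_len(2^n - 1), function(mask) {
    sum(weights[bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) > 0])
  }, numeric(1))
  cost <- function(mask) {
    key <- as.character(mask)
    if (!is.null(memo[[key]])) return(memo[[key]])
    members <- which(bitwAnd(mask, bitwShiftL(1, seq_len(n) - 1)) > 0)
    if (length(members) == 1L) return(0)
    best <- Inf
    # iterate proper non-empty submasks of mask
    sub <- bitwAnd(mask - 1, mask)
    while (sub > 0) {
      other <- mask - sub
      if (sub < other) { # each partition once
        best <- min(best, cost(sub) + cost(other))
      }
      sub <- bitwAnd(sub - 1, mask)
    }
    res <- subset_weight[mask] + best
    memo[[key]] <- res
    res
  }
  cost(2^n - 1)
}

# Connected components by per-node breadth-first search over an adjacency
# list; returns sorted list of sorted groups.
reachability_groups <- function(edges, all_genes) {
  adj <- setNames(vector("list", length(all_genes)), all_genes)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  groups <- list()
  for (g in all_genes) {
    if (g %in% seen) next
    frontier <- g; comp <- character(0)
    while (length(frontier)) {
      x <- frontier[1]; frontier <- frontier[-1]
      if (x %in% comp) next
      comp <- c(comp, x)
      frontier <- c(frontier, setdiff(adj[[x]], comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    groups[[length(groups) + 1L]] <- comp
  }
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

# Average precision for tie-free scores: mean over positives of the
# precision at that positive's rank.
ap_rank_oracle <- function(labels, scores) {
  stopifnot(!any(duplicated(scores)))
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  ranks_pos <- which(lab == 1)
  mean(vapply(ranks_pos, function(r) sum(lab[1:r]) / r, numeric(1)))
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (no ties, no zeros).
wilcoxon_exact_oracle <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# Brute-force decoupled contrastive loss: literal double sum.
dcl_brute_force <- function(z1, z2, tau, w = 1) {
  N <- nrow(z1)
  w <- rep_len(w, N)
  per_sample <- vapply(seq_len(N), function(i) {
    acc <- 0
    for (k in seq_len(N)) {
      if (k == i) next
      acc <- acc + exp(sum(z1[i, ] * z1[k, ]) / tau)
      acc <- acc + exp(sum(z1[i, ] * z2[k, ]) / tau)
    }
    log(acc) - w[i] * sum(z1[i, ] * z2[i, ]) / tau
  }, numeric(1))
  mean(per_sample)
}

# Random probability vector of given size (Dirichlet(1) via normalized
# exponentials).
random_distribution <- function(n) {
  x <- -log(runif(n))
  x / sum(x)
}
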