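#' Masked-language-model loss
#'
#' Negative log-likelihood of the true tokens at the masked positions:
#' `-sum(log p_t)` over `t` in the masked set, natural log. `token_probs`
#' holds, per position, the probability the model assigned to the *true*
#' token given the unmasked context.
#'
#' @param token_probs Numeric vector of per-position probabilities in
#'   `(0, 1]`.
#' @param masked_positions Integer indices of the masked positions
#'   (non-empty subset of `seq_along(token_probs)`).
#' @return Non-negative scalar loss.
#' @examples
#' mlm_loss(c(0.5, 1), 1)      # log(2)
#' mlm_loss(c(0.5, 0.5), 1:2)  # 2 * log(2)
#' @export
mlm_loss <- function(token_probs, masked_positions = seq_along(token_probs)) {
  if (!length(masked_positions)) stop("masked position set must be non-empty")
  if (any(masked_positions < 1L | masked_positions > length(token_probs)))
    stop("masked_positions outside the sequence")
  p <- token_probs[masked_positions]
  if (any(p <= 0)) stop("infinite loss: zero probability at a masked position")
  if (any(p > 1)) stop("token probabilities must be in (0, 1]")
  -sum(log(p))
}

#' Decoupled contrastive loss
#'
#' Two views per sample; the loss for sample `i`, anchored on its first
#' view, is
#' `log sum_{k != i} sum_{l in 1,2} exp(<z_i^1, z_k^l> / tau)
#'  - w_i * <z_i^1, z_i^2> / tau`,
#' i.e. the positive pair is *decoupled* from the normalizing sum (both
#' views of sample `i` are excluded from the negatives). Similarity is
#' the plain inner product of the rows as given; normalize rows first for
#' cosine similarity. The batch loss is the mean over samples.
#'
#' @param z1,z2 `N x d` matrices; row `i` holds the two views of sample
#'   `i`. `N >= 2`.
#' @param tau Temperature (> 0).
#' @param w Per-sample positive weights (scalar or length `N`; default 1).
#' @param symmetric If `TRUE`, average the loss anchored on view 1 with
#'   the loss anchored on view 2 (off by default; the printed form is
#'   view-1 anchored).
#' @return Scalar batch loss.
#' @export
dcl_loss <- function(z1, z2, tau = 1, w = 1, symmetric = FALSE) {
  z1 <- as.matrix(z1); z2 <- as.matrix(z2)
  if (!all(dim(z1) == dim(z2))) stop("z1 and z2 must have identical shape")
  N <- nrow(z1)
  if (N < 2L) stop("empty negative set: need at least 2 samples")
  if (tau <= 0) stop("temperature must be > 0")
  if (!all(is.finite(z1)) || !all(is.finite(z2))) stop("non-finite views")
  w <- rep_len(w, N)
  anchor_loss <- function(za, zb) {
    s1 <- za %*% t(za) / tau   # anchor vs view-a of all samples
    s2 <- za %*% t(zb) / tau   # anchor vs view-b of all samples
    pos <- diag(s2)
    neg <- vapply(seq_len(N), function(i) {
      terms <- c(s1[i, -i], s2[i, -i])
      m <- max(terms)
      m + log(sum(exp(terms - m)))
    }, numeric(1))
    mean(neg - w * pos)
  }
  if (symmetric) {
    (anchor_loss(z1, z2) + anchor_loss(z2, z1)) / 2
  } else {
    anchor_loss(z1, z2)
  }
}

#' Scalarized joint pre-training objective
#'
#' Fixed linear mixing of the two self-supervised losses:
#' `alpha * l_mlm + (1 - alpha) * l_cl`. `alpha = 1` is MLM-only,
#' `alpha = 0` contrastive-only.
#'
#' @param alpha Mixing weight in `[0, 1]`.
#' @param l_mlm,l_cl The two loss values.
#' @return The combined loss.
#' @export
scalarized_loss <- function(alpha, l_mlm, l_cl) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  alpha * l_mlm + (1 - alpha) * l_cl
}

# ---- desk-scale demonstration: joint objective on a toy encoder --------

# Mutate a sequence per site with probability `rate` (uniform different
# base) — used to create contrastive views.
mutate_sequence <- function(seq, rate) {
  s <- strsplit(seq, "")[[1]]
  hit <- runif(length(s)) < rate
  if (any(hit))
    s[hit] <- vapply(s[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
  paste(s, collapse = "")
}

#' Train a toy encoder under the scalarized MLM + contrastive objective
#'
#' A deliberately tiny model for studying how the objective mix shapes
#' representations, far below pre-training scale but using the exact loss
#' functions above. Sequences are featurized as dinucleotide frequencies
#' `f` (16-dim); the encoder is `z = tanh(U f)` with a `d`-dimensional
#' bottleneck. The MLM head predicts each masked base from the sequence
#' embedding via softmax(`B z + b`), scored by [mlm_loss()]; the
#' contrastive term applies [dcl_loss()] to row-normalized embeddings of
#' two views of each sequence — by default two independently mutated
#' copies, or caller-supplied related sequences (e.g. paralogs, mirroring
#' orthology-style augmentation). Training minimizes
#' `scalarized_loss(alpha, mlm_per_masked_position, dcl)` with L-BFGS.
#'
#' @param sequences Character vector of training sequences.
#' @param alpha Objective mix in `[0, 1]` (1 = MLM-only).
#' @param d Embedding dimension (default 4).
#' @param view_mut_rate Per-site mutation rate for the default views.
#' @param views Optional list of two character vectors (same length as
#'   `sequences`) supplying the contrastive views explicitly.
#' @param n_masked Masked positions per sequence for the MLM term.
#' @param tau DCL temperature.
#' @param iters L-BFGS iteration budget.
#' @param weight_decay L2 penalty on the parameters (default 0.05). Keeps
#'   the learned representation minimal for its training objective —
#'   directions the objective does not reward are shrunk away rather than
#'   surviving from the random initialization.
#' @param seed Integer seed (views, masks and initialization).
#' @return List of class `"toy_encoder"`: `U`, `B`, `b`, `alpha`, and
#'   `embed(seqs)` returning the `n x d` embedding matrix.
#' @export
train_toy_encoder <- function(sequences, alpha, d = 4, view_mut_rate = 0.1,
                              n_masked = 8, tau = 0.5, iters = 60,
                              weight_decay = 0.05, views = NULL, seed = 1) {
  stopifnot(length(sequences) >= 4L)
  set.seed(seed)
  n <- length(sequences)
  feats <- function(seqs) {
    m <- t(vapply(seqs, count_kmers_one, numeric(16L), k = 2L,
                  kmers = all_kmers(2)))
    m / pmax(rowSums(m), 1)
  }
  F0 <- t(feats(sequences))                       # 16 x n
  if (is.null(views)) {
    v1 <- vapply(sequences, mutate_sequence, character(1),
                 rate = view_mut_rate)
    v2 <- vapply(sequences, mutate_sequence, character(1),
                 rate = view_mut_rate)
  } else {
    stopifnot(length(views) == 2L, lengths(views) == n)
    v1 <- views[[1]]; v2 <- views[[2]]
  }
  F1 <- t(feats(v1)); F2 <- t(feats(v2))
  # fixed masked positions and their true bases
  base_idx <- lapply(sequences, function(s) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample.int(length(ch), min(n_masked, length(ch)))
    match(ch[pos], DNA_BASES)
  })
  true_base <- unlist(base_idx)
  seq_of_pos <- rep(seq_len(n), lengths(base_idx))

  unpack <- function(par) {
    U <- matrix(par[1:(d * 16L)], d, 16L)
    B <- matrix(par[d * 16L + 1:(4L * d)], 4L, d)
    b <- par[d * 16L + 4L * d + 1:4L]
    list(U = U, B = B, b = b)
  }
  row_normalize <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)
  objective <- function(par) {
    pr <- unpack(par)
    Z0 <- tanh(pr$U %*% F0)
    logits <- pr$B %*% Z0 + pr$b                  # 4 x n
    lse <- apply(logits, 2L, function(v) max(v) + log(sum(exp(v - max(v)))))
    logp <- logits[cbind(true_base, seq_of_pos)] - lse[seq_of_pos]
    l_mlm <- mlm_loss(exp(logp)) / length(logp)
    Z1 <- row_normalize(t(tanh(pr$U %*% F1)))
    Z2 <- row_normalize(t(tanh(pr$U %*% F2)))
    l_cl <- dcl_loss(Z1, Z2, tau = tau)
    scalarized_loss(alpha, l_mlm, l_cl) + weight_decay * mean(par^2)
  }
  par0 <- rnorm(d * 16L + 4L * d + 4L, sd = 0.3)
  fit <- optim(par0, objective, method = "L-BFGS-B",
               control = list(maxit = iters))
  pr <- unpack(fit$par)
  structure(list(U = pr$U, B = pr$B, b = pr$b, alpha = alpha,
                 value = fit$value,
                 embed = function(seqs) t(tanh(pr$U %*% t(feats(seqs))))),
            class = "toy_encoder")
}

#' Sweep the objective mix and score a global task by linear probing
#'
#' Emulates the objective-mixing experiment at desk scale: sequences come
#' from paralog-like families whose (hidden) family value is the global
#' regression label; for each `alpha` a [train_toy_encoder()] model is
#' fitted and its frozen embeddings probed under a random split. The
#' contrastive positive pair is a sequence and a *paralog-family sibling*
#' (orthology-style augmentation), so contrastive signal makes family
#' identity linearly decodable, whereas base-composition statistics (all
#' an MLM head needs here) separate families poorly. The expected shape
#' is therefore a global-task score that *improves* as soon as
#' contrastive signal is mixed in at `alpha < 1`.
#'
#' @param alphas Mixing weights to sweep (should include 1).
#' @param n_families,family_size,seq_len Family design of the synthetic
#'   corpus.
#' @param n_probe_seeds Random probe splits averaged per alpha.
#' @param n_encoder_seeds Independent encoder initializations averaged per
#'   alpha (the toy optimization is non-convex, so a single run is noisy).
#' @param seed Integer seed.
#' @param ... Passed on to [train_toy_encoder()].
#' @return Data frame `alpha`, `global_r` (mean probe test Pearson r).
#' @export
sweep_objective_mix <- function(alphas = c(1, 0.75, 0.5, 0.25),
                                n_families = 12, family_size = 6,
                                seq_len = 120, n_probe_seeds = 3,
                                n_encoder_seeds = 3, seed = 1, ...) {
  fam <- simulate_paralog_families(n_families, family_size, seq_len,
                                   target_identity = 0.92, seed = seed)
  seqs <- vapply(fam$transcripts, `[[`, character(1), "sequence")
  ids <- vapply(fam$transcripts, `[[`, character(1), "id")
  names(seqs) <- ids
  set.seed(derive_seed(seed, "family_values"))
  fam_value <- rnorm(n_families)
  y <- setNames(fam_value[as.integer(fam$family[ids])], ids)
  # orthology-style views: each sample paired with a family sibling
  sibling_of <- vapply(ids, function(id) {
    sibs <- setdiff(ids[fam$family[ids] == fam$family[[id]]], id)
    if (length(sibs)) sample(sibs, 1L) else id
  }, character(1))
  views <- list(unname(seqs[ids]), unname(seqs[sibling_of]))
  task <- task_spec("family_value", "regression", locality = "global")
  res <- lapply(alphas, function(a) {
    per_enc <- vapply(seq_len(n_encoder_seeds), function(es) {
      enc <- train_toy_encoder(seqs, alpha = a, views = views,
                               seed = derive_seed(seed, paste0("encoder", es)),
                               ...)
      emb <- enc$embed(seqs)
      rownames(emb) <- ids
      rs <- vapply(seq_len(n_probe_seeds), function(s) {
        sp <- random_split(ids, 0.3, derive_seed(seed, paste0("probe", s)))
        tr <- split_ids(sp, "train"); te <- split_ids(sp, "test")
        fit_and_score_probe(
          list(embeddings = emb[tr, , drop = FALSE], labels = y[tr]),
          list(embeddings = emb[te, , drop = FALSE], labels = y[te]),
          task, regularization = 0.1)$value
      }, numeric(1))
      mean(rs)
    }, numeric(1))
    mean(per_enc)
  })
  data.frame(alpha = alphas, global_r = unlist(res))
}
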