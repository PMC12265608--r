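#' Describe a region-specific sequence grammar
#'
#' Different genomic regions (CDS, UTRs, intergenic DNA, ...) have distinct
#' low-order sequence statistics. A grammar is either an order-0/order-1
#' Markov chain over single nucleotides, or — for coding sequence — a codon
#' usage table that overrides Markov sampling with i.i.d. codons.
#'
#' @param name Region name.
#' @param order Markov order, 0 or 1 (ignored when `codon_usage` given).
#' @param initial_probs Length-4 distribution over A,C,G,T.
#' @param transition_probs 4x4 row-stochastic matrix (order 1 only).
#' @param codon_usage Optional named length-64 distribution over codons.
#' @return Object of class `"region_grammar_spec"`.
#' @export
region_grammar_spec <- function(name, order = 0,
                                initial_probs = rep(0.25, 4),
                                transition_probs = NULL,
                                codon_usage = NULL) {
  stopifnot(order %in% c(0, 1))
  if (length(initial_probs) != 4L || abs(sum(initial_probs) - 1) > 1e-9)
    stop("initial_probs must be a length-4 distribution summing to 1")
  if (order == 1) {
    if (is.null(transition_probs)) stop("order-1 grammar needs transition_probs")
    transition_probs <- as.matrix(transition_probs)
    if (!all(dim(transition_probs) == c(4L, 4L)))
      stop("transition_probs must be 4x4")
    if (any(abs(rowSums(transition_probs) - 1) > 1e-9))
      stop("transition_probs rows must each sum to 1")
  }
  if (!is.null(codon_usage)) {
    if (length(codon_usage) != 64L || abs(sum(codon_usage) - 1) > 1e-9)
      stop("codon_usage must be a length-64 distribution summing to 1")
    if (is.null(names(codon_usage))) names(codon_usage) <- all_kmers(3)
  }
  structure(list(name = name, order = order, initial_probs = initial_probs,
                 transition_probs = transition_probs,
                 codon_usage = codon_usage),
            class = "region_grammar_spec")
}

#' Sample sequences from a Markov region grammar
#'
#' @param spec A [region_grammar_spec()] (Markov mode; a codon-usage spec
#'   should use [simulate_cds_region()]).
#' @param n Number of sequences.
#' @param length_range Length-2 vector `c(min, max)`; lengths are drawn
#'   uniformly on that range (inclusive).
#' @param seed Integer seed; output is bit-reproducible given the same
#'   spec, n, range and seed.
#' @return Character vector of `n` sequences.
#' @export
simulate_markov_region <- function(spec, n, length_range, seed) {
  stopifnot(inherits(spec, "region_grammar_spec"), is_count(n))
  if (length(length_range) != 2L || length_range[1] > length_range[2])
    stop("length_range must be c(min, max) with min <= max")
  set.seed(seed)
  lens <- sample.int(length_range[2] - length_range[1] + 1L, n,
                     replace = TRUE) + length_range[1] - 1L
  vapply(lens, function(L) {
    if (spec$order == 0) {
      paste(sample_discrete(DNA_BASES, spec$initial_probs, L), collapse = "")
    } else {
      idx <- integer(L)
      idx[1] <- sample.int(4L, 1L, prob = spec$initial_probs)
      if (L > 1) for (i in 2:L)
        idx[i] <- sample.int(4L, 1L, prob = spec$transition_probs[idx[i - 1], ])
      paste(DNA_BASES[idx], collapse = "")
    }
  }, character(1))
}

#' Sample coding-like sequences from a codon usage table
#'
#' Each sequence is `n_codons` codons drawn i.i.d. from `codon_usage`, so
#' the 3-periodic structure of real CDS (which drives its compressibility)
#' is present while everything else is random.
#'
#' @param codon_usage Named length-64 distribution over codons (names
#'   default to the lexicographic codon order).
#' @param n Number of sequences.
#' @param n_codons Codons per sequence (length is `3 * n_codons`).
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
simulate_cds_region <- function(codon_usage, n, n_codons, seed) {
  if (abs(sum(codon_usage) - 1) > 1e-9)
    stop("codon_usage must sum to 1")
  if (!is_count(n_codons)) stop("n_codons must be a positive integer")
  if (is.null(names(codon_usage))) names(codon_usage) <- all_kmers(3)
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample_discrete(names(codon_usage), codon_usage, n_codons),
          collapse = "")
  }, character(1))
}

#' Simulate paralog families with known truth edges
#'
#' Each family starts from a uniformly random ancestor; every member is an
#' independent copy mutated per site with probability
#' `1 - target_identity` (substitution to a uniformly chosen *different*
#' base; no indels). The identity of a member to its ancestor is therefore
#' `target_identity` in expectation, while two members of the same family
#' match at `(1-mu)^2 + mu^2/3` per site with `mu = 1 - target_identity`.
#' All within-family gene pairs are returned as truth edges, mimicking a
#' curated paralog table.
#'
#' @param n_families Number of families.
#' @param family_size Members per family (each member is its own gene with
#'   one transcript).
#' @param seq_len Sequence length.
#' @param target_identity Expected member-to-ancestor identity in `(0, 1]`.
#' @param seed Integer seed.
#' @return List with `transcripts` (list of [transcript()]; ids `famF_mM`,
#'   gene per member), `edges` (a [paralog_edges()] table of within-family
#'   pairs with their realized positional identity), and `family` (named
#'   vector id -> family index).
#' @export
simulate_paralog_families <- function(n_families, family_size, seq_len,
                                      target_identity, seed) {
  stopifnot(is_count(n_families), is_count(family_size), is_count(seq_len))
  if (!(target_identity > 0 && target_identity <= 1))
    stop("target_identity must be in (0, 1]")
  set.seed(seed)
  mu <- 1 - target_identity
  transcripts <- list()
  family <- character(0)
  edges <- list()
  for (f in seq_len(n_families)) {
    anc <- sample(DNA_BASES, seq_len, replace = TRUE)
    members <- vector("list", family_size)
    for (m in seq_len(family_size)) {
      s <- anc
      hit <- runif(seq_len) < mu
      if (any(hit)) {
        # substitute each hit site with one of the three other bases
        s[hit] <- vapply(s[hit], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
      }
      id <- sprintf("fam%d_m%d", f, m)
      members[[m]] <- transcript(id, paste(s, collapse = ""), gene_id = id,
                                 chromosome = sprintf("chr%d", (f %% 5) + 1))
      family[id] <- f
    }
    transcripts <- c(transcripts, members)
    if (family_size > 1) {
      for (a in seq_len(family_size - 1)) for (b in (a + 1):family_size) {
        edges[[length(edges) + 1L]] <- data.frame(
          gene_a = sprintf("fam%d_m%d", f, a),
          gene_b = sprintf("fam%d_m%d", f, b),
          identity = pairwise_identity(members[[a]]$sequence,
                                       members[[b]]$sequence))
      }
    }
  }
  edge_df <- if (length(edges)) do.call(rbind, edges) else
    data.frame(gene_a = character(0), gene_b = character(0),
               identity = numeric(0))
  list(transcripts = transcripts, edges = paralog_edges(edge_df),
       family = family)
}

#' Label sequences by occurrence of a planted motif
#'
#' Binary tasks get `1` iff the motif occurs anywhere; regression tasks get
#' `effect * count + Gaussian noise`, where `count` is the number of
#' (possibly overlapping) occurrences. RBP-style motifs of 4-7 nt are the
#' intended use.
#'
#' @param sequences Named character vector (names are transcript ids).
#' @param motif Motif over A,C,G,T.
#' @param task A [task_spec()] of kind `"binary"` or `"regression"`.
#' @param effect Regression effect size per occurrence.
#' @param noise_sd Regression noise standard deviation.
#' @param seed Integer seed (used only for regression noise).
#' @return Data frame `id`, `label`.
#' @export
simulate_motif_labels <- function(sequences, motif, task, effect = 1,
                                  noise_sd = 0, seed = 1) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (grepl("[^ACGT]", motif)) stop("motif must be over A,C,G,T")
  stopifnot(inherits(task, "task_spec"))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  counts <- vapply(sequences, count_motif, integer(1), motif = motif)
  label <- if (task$kind == "binary") {
    as.numeric(counts > 0)
  } else if (task$kind == "regression") {
    set.seed(seed)
    effect * counts + rnorm(length(counts), 0, noise_sd)
  } else stop("motif labels support binary and regression tasks")
  data.frame(id = names(sequences), label = label)
}

#' Specify the MPRA ribosome-load label model
#'
#' Mean ribosome load (MRL) of a reporter 5'UTR is modelled on two
#' regulatory features: Kozak context strength around the main start codon
#' (enhancing) and upstream AUGs (suppressing), with an optional
#' interaction:
#' `y = beta0 + beta_kozak * s - beta_uaug * c + gamma * s * c + noise`,
#' where in the default binary mode `s = 1[strong Kozak]` and
#' `c = 1[uAUG present]`, and in graded mode `s` is a continuous Kozak
#' strength score and `c` the uAUG count.
#'
#' @param beta0 Baseline load.
#' @param beta_kozak Effect of Kozak strength.
#' @param beta_uaug Magnitude of uAUG suppression (entered with a minus
#'   sign).
#' @param gamma Interaction coefficient.
#' @param noise_sd Gaussian noise SD (>= 0).
#' @return Object of class `"mpra_label_model"`.
#' @export
mpra_label_model <- function(beta0 = 5, beta_kozak = 2, beta_uaug = 2,
                             gamma = 0, noise_sd = 0.1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(beta0 = beta0, beta_kozak = beta_kozak,
                 beta_uaug = beta_uaug, gamma = gamma, noise_sd = noise_sd),
            class = "mpra_label_model")
}

mpra_label <- function(model, s, c_) {
  model$beta0 + model$beta_kozak * s - model$beta_uaug * c_ +
    model$gamma * s * c_
}

#' Simulate an MPRA 5'UTR library over the Kozak x uAUG design
#'
#' Generates `n_per_cell` reporter constructs in each of the four cells of
#' the two-factor design (Kozak strong/weak x uAUG absent/present). The
#' emitted sequence is the 5'UTR followed by the main start codon and a
#' short CDS stub; the Kozak rule (purine at -3, G at +4) and the uAUG
#' guarantee (no ATG anywhere in the UTR of uAUG-free cells, >= 1 planted
#' ATG otherwise) hold by construction. Labels follow the
#' [mpra_label_model()] exactly.
#'
#' In binary mode (`graded = FALSE`) the model's `s` and `c` are the cell
#' indicators, so labels are constant within a cell up to noise. In graded
#' mode, `s` is drawn uniformly within a strong (`[0.7, 1]`) or weak
#' (`[0, 0.3]`) band and `c` is the planted uAUG count (1-3 in uAUG
#' cells), so labels vary *within* cells — the regime in which a
#' compositional-generalization probe is meaningful.
#'
#' @param n_per_cell Constructs per design cell.
#' @param model An [mpra_label_model()].
#' @param utr_len 5'UTR length (>= 10).
#' @param seed Integer seed.
#' @param graded Use graded Kozak score / uAUG count (default `FALSE`).
#' @return A [labeled_dataset()] (regression task `"mrl"`) with an extra
#'   element `annotations`: data frame `id`, `has_uaug`, `kozak`,
#'   `uaug_count`, `kozak_score`.
#' @export
simulate_mpra_utrs <- function(n_per_cell, model, utr_len = 50, seed = 1,
                               graded = FALSE) {
  stopifnot(inherits(model, "mpra_label_model"), is_count(n_per_cell))
  if (utr_len < 10) stop("utr_len must be >= 10")
  set.seed(seed)
  cells <- expand.grid(kozak = c("strong", "weak"), uaug = c(0L, 1L),
                       stringsAsFactors = FALSE)
  recs <- list(); ann <- list(); labs <- list()
  idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    kz <- cells$kozak[ci]; ua <- cells$uaug[ci]
    for (r in seq_len(n_per_cell)) {
      idx <- idx + 1L
      id <- sprintf("utr%04d", idx)
      count <- if (ua == 1L) { if (graded) sample(1:3, 1L) else 1L } else 0L
      utr <- make_utr(utr_len, kz, count)
      score <- if (graded) {
        if (kz == "strong") runif(1, 0.7, 1) else runif(1, 0, 0.3)
      } else as.numeric(kz == "strong")
      c_ <- if (graded) count else as.numeric(ua == 1L)
      y <- mpra_label(model, score, c_) + rnorm(1, 0, model$noise_sd)
      # sequence: UTR + main ATG + 5 codons of stop-free CDS stub; the +4
      # base (first CDS base) carries the Kozak +4 rule.
      plus4 <- if (kz == "strong") "G" else "C"
      stub <- paste0(plus4, "CTGGTCTGCTGGTC")
      cds_start <- nchar(utr)
      recs[[idx]] <- transcript(id, paste0(utr, "ATG", stub),
                                cds = c(cds_start, cds_start + 18L))
      ann[[idx]] <- data.frame(id = id, has_uaug = ua == 1L, kozak = kz,
                               uaug_count = count, kozak_score = score)
      labs[[idx]] <- data.frame(id = id, mrl = y)
    }
  }
  ds <- labeled_dataset(recs, do.call(rbind, labs),
                        task_spec("mrl", "regression", locality = "local"))
  ds$annotations <- do.call(rbind, ann)
  ds
}

# Build one 5'UTR: no ATG anywhere unless n_uaug > 0, in which case exactly
# n_uaug planted ATGs (in the 5' half, clear of the Kozak -6..-1 context);
# the final 3 nt encode the -3..-1 Kozak context per `kozak`.
make_utr <- function(utr_len, kozak, n_uaug) {
  repeat {
    s <- sample(DNA_BASES, utr_len, replace = TRUE)
    # -3 position rule (purine = strong, pyrimidine = weak)
    s[utr_len - 2L] <- if (kozak == "strong") sample(c("A", "G"), 1L) else
      sample(c("C", "T"), 1L)
    str <- paste(s, collapse = "")
    # scrub any accidental ATG (also re-check after scrubbing)
    for (pass in 1:10) {
      hit <- regexpr("ATG", str, fixed = TRUE)
      if (hit == -1L) break
      substr(str, hit + 2L, hit + 2L) <- sample(c("A", "C"), 1L)
    }
    if (grepl("ATG", str, fixed = TRUE)) next
    if (n_uaug > 0) {
      # plant in the 5' portion, away from the -6..-1 context and from
      # each other (slots every 4 nt)
      avail <- utr_len - 9L
      if (avail < 3L * n_uaug) stop("utr_len too short for requested uAUGs")
      slots <- sort(sample(seq.int(1L, avail, by = 3L), n_uaug))
      for (p in slots) substr(str, p, p + 2L) <- "ATG"
      if (count_motif(str, "ATG") != n_uaug) next
    }
    # -3 rule must have survived scrubbing
    minus3 <- substr(str, utr_len - 2L, utr_len - 2L)
    ok <- if (kozak == "strong") minus3 %in% c("A", "G") else
      minus3 %in% c("C", "T")
    if (ok) return(str)
  }
}

#' Embed sequences as k-mer count vectors
#'
#' A deterministic toy embedder standing in for a frozen foundation model:
#' each sequence maps to its vector of overlapping k-mer counts (columns in
#' fixed lexicographic order), optionally normalized to frequencies.
#' Linearly decodable properties of k-mer composition — such as presence of
#' a planted motif — are thus exposed to a linear probe.
#'
#' @param sequences Named character vector (names become ids).
#' @param k Word length.
#' @param normalize Divide each row by its total count (default `TRUE`).
#' @return An [embedding_matrix()] with `4^k` columns.
#' @export
kmer_count_embed <- function(sequences, k, normalize = TRUE) {
  if (!is_count(k)) stop("k must be a positive integer")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  short <- names(sequences)[nchar(sequences) < k]
  if (length(short))
    stop("sequence(s) shorter than k: ", paste(head(short, 5), collapse = ", "))
  kmers <- all_kmers(k)
  vals <- t(vapply(sequences, count_kmers_one, numeric(length(kmers)),
                   k = k, kmers = kmers))
  if (normalize) {
    tot <- rowSums(vals)
    tot[tot == 0] <- 1
    vals <- vals / tot
  }
  colnames(vals) <- kmers
  embedding_matrix(names(sequences), vals)
}
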