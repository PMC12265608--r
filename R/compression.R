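#' Tokenize a sequence into non-overlapping k-nucleotide blocks
#'
#' Blocks are taken left to right; a trailing remainder shorter than `k`
#' is dropped, as is any block containing an ambiguous base (N). The
#' number of dropped nucleotides/blocks is attached as attributes.
#'
#' @param seq Character scalar.
#' @param k Block width in nucleotides.
#' @return Character vector of tokens with attributes `"dropped_nt"`
#'   (trailing remainder length) and `"dropped_n_blocks"` (blocks removed
#'   for containing N).
#' @export
tokenize_blocks <- function(seq, k) {
  if (!is_count(k)) stop("k must be a positive integer")
  L <- nchar(seq)
  n_blocks <- L %/% k
  if (n_blocks == 0L) {
    out <- character(0)
  } else {
    starts <- seq.int(1L, by = k, length.out = n_blocks)
    out <- substring(seq, starts, starts + k - 1L)
  }
  keep <- !grepl("N", out, fixed = TRUE)
  res <- out[keep]
  attr(res, "dropped_nt") <- L - n_blocks * k
  attr(res, "dropped_n_blocks") <- sum(!keep)
  res
}

# Deterministic Huffman code over a named frequency vector (positive mass
# only). Ties in the merge queue are broken by the lexicographically
# smallest token contained in each subtree, so identical inputs always
# yield byte-identical codebooks.
huffman_code <- function(freqs) {
  freqs <- freqs[freqs > 0]
  tokens <- names(freqs)
  if (length(tokens) < 2L)
    stop("Huffman coding needs at least 2 distinct tokens")
  ord <- order(tokens)
  nodes <- lapply(ord, function(i) list(w = freqs[[i]], key = tokens[i],
                                        leaves = tokens[i]))
  codes <- setNames(rep("", length(tokens)), tokens)
  while (length(nodes) > 1L) {
    ws <- vapply(nodes, `[[`, numeric(1), "w")
    ks <- vapply(nodes, `[[`, character(1), "key")
    pick <- order(ws, ks)[1:2]
    a <- nodes[[pick[1]]]; b <- nodes[[pick[2]]]
    codes[a$leaves] <- paste0("0", codes[a$leaves])
    codes[b$leaves] <- paste0("1", codes[b$leaves])
    merged <- list(w = a$w + b$w, key = min(a$key, b$key),
                   leaves = c(a$leaves, b$leaves))
    nodes <- c(nodes[-pick], list(merged))
  }
  codes
}

#' Build a Huffman grammar from a region corpus
#'
#' Token frequencies are `(count + pseudo_count) / total` over all `4^k`
#' possible k-blocks; with a positive pseudo-count every token receives a
#' codeword, so the grammar can encode *any* corpus (required for
#' cross-region compression). Frequent tokens receive short codewords;
#' the realized code length approximates the corpus entropy.
#'
#' @param corpus Character vector of sequences.
#' @param k Token width in nucleotides (default 3, the codon width —
#'   coding sequence owes its compressibility to codon structure, which
#'   single-nucleotide tokens cannot see).
#' @param pseudo_count Pseudo-count added to every possible token
#'   (default 1). With `pseudo_count = 0`, only observed tokens are coded
#'   and unseen tokens later raise an error.
#' @param source_name Region name recorded on the grammar.
#' @return Object of class `"huffman_grammar"`: `k`, `codebook` (token ->
#'   bit string), `freqs`, `pseudo_count`, `source_name`.
#' @export
build_huffman_grammar <- function(corpus, k = 3, pseudo_count = 1,
                                  source_name = "corpus") {
  if (!is_count(k)) stop("k must be a positive integer")
  if (pseudo_count < 0) stop("pseudo_count must be >= 0")
  tokens <- all_kmers(k)
  counts <- setNames(numeric(length(tokens)), tokens)
  for (s in corpus) {
    tk <- tokenize_blocks(s, k)
    if (length(tk)) {
      tab <- table(tk)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts <- counts + pseudo_count
  if (sum(counts > 0) < 2L)
    stop("empty model: corpus yields fewer than 2 distinct tokens ",
         "(use pseudo_count > 0)")
  freqs <- counts / sum(counts)
  codebook <- huffman_code(freqs)
  structure(list(k = k, codebook = codebook, freqs = freqs[freqs > 0],
                 pseudo_count = pseudo_count, source_name = source_name),
            class = "huffman_grammar")
}

#' @export
print.huffman_grammar <- function(x, ...) {
  cat("<huffman_grammar> '", x$source_name, "': ", length(x$codebook),
      " tokens of width ", x$k, ", pseudo-count ", x$pseudo_count, "\n",
      "  expected code length ", sprintf("%.4f", expected_code_length(x)),
      " bits/token (entropy ", sprintf("%.4f", grammar_entropy(x)), ")\n",
      sep = "")
  invisible(x)
}

#' Expected code length of a grammar, in bits per token
#'
#' @param grammar A [build_huffman_grammar()] result.
#' @return `sum(freqs * codeword lengths)`; lies in `[H, H + 1)` where `H`
#'   is [grammar_entropy()].
#' @export
expected_code_length <- function(grammar) {
  sum(grammar$freqs * nchar(grammar$codebook[names(grammar$freqs)]))
}

#' Shannon entropy of a grammar's token distribution (bits/token)
#'
#' @param grammar A [build_huffman_grammar()] result.
#' @return Entropy in bits.
#' @export
grammar_entropy <- function(grammar) {
  p <- grammar$freqs[grammar$freqs > 0]
  -sum(p * log2(p))
}

#' Code length of a corpus under a grammar
#'
#' Tokenizes with the grammar's own `k`, sums codeword lengths, and
#' compares against the trivial 2-bits-per-nucleotide baseline.
#'
#' @param grammar A [build_huffman_grammar()] result.
#' @param corpus Character vector of sequences.
#' @return Object of class `"compression_result"`: `coded_bits`,
#'   `baseline_bits` (`2 * k * token count`), `ratio`
#'   (`coded / baseline`), `n_tokens`.
#' @export
encoded_length <- function(grammar, corpus) {
  stopifnot(inherits(grammar, "huffman_grammar"))
  lens <- setNames(nchar(grammar$codebook), names(grammar$codebook))
  coded <- 0; n_tok <- 0L
  for (s in corpus) {
    tk <- tokenize_blocks(s, grammar$k)
    if (!length(tk)) next
    unseen <- setdiff(unique(tk), names(lens))
    if (length(unseen))
      stop("token '", unseen[1], "' has no codeword (grammar built with ",
           "pseudo_count = 0 cannot cross-compress)")
    coded <- coded + sum(lens[tk])
    n_tok <- n_tok + length(tk)
  }
  if (n_tok == 0L) stop("empty input: no tokens to encode")
  baseline <- 2 * grammar$k * n_tok
  structure(list(coded_bits = as.numeric(coded), baseline_bits = baseline,
                 ratio = coded / baseline, n_tokens = n_tok),
            class = "compression_result")
}

#' @export
print.compression_result <- function(x, ...) {
  cat("<compression_result> ", x$coded_bits, " / ", x$baseline_bits,
      " bits (ratio ", sprintf("%.4f", x$ratio), ", ", x$n_tokens,
      " tokens)\n", sep = "")
  invisible(x)
}

#' Compression ratio of a target corpus under a source-region grammar
#'
#' Builds the grammar on `source_corpus`, encodes `target_corpus`, and
#' returns coded bits over the 2-bit baseline. With `source == target`
#' this is the region's self-compression ratio; across regions the excess
#' over the target's self-ratio measures distributional shift (a
#' cross-entropy versus entropy gap, so it is non-negative up to sampling
#' error).
#'
#' @inheritParams build_huffman_grammar
#' @param source_corpus Sequences the grammar is estimated from.
#' @param target_corpus Sequences being encoded.
#' @return Numeric ratio.
#' @export
compression_ratio <- function(source_corpus, target_corpus, k = 3,
                              pseudo_count = 1) {
  g <- build_huffman_grammar(source_corpus, k, pseudo_count)
  encoded_length(g, target_corpus)$ratio
}

#' Cross-compression matrix over named region corpora
#'
#' Entry `(i, j)` is the compression ratio of region `j`'s corpus under
#' region `i`'s grammar. The percent-increase matrix rescales each column
#' by its diagonal: `100 * (ratio(i,j) - ratio(j,j)) / ratio(j,j)`, i.e.
#' how much worse region `i`'s code does on region `j` than region `j`'s
#' own code — zero on the diagonal by construction.
#'
#' @param corpora Named list (>= 2) of character vectors of sequences.
#' @param k Token width.
#' @param pseudo_count Pseudo-count for every grammar.
#' @return Object of class `"cross_compression"`: `ratios` and
#'   `percent_increase`, both source x target matrices.
#' @export
cross_compression_matrix <- function(corpora, k = 3, pseudo_count = 1) {
  if (length(corpora) < 2L) stop("need at least 2 corpora")
  if (is.null(names(corpora))) stop("corpora must be named")
  nm <- names(corpora)
  grammars <- lapply(nm, function(r)
    build_huffman_grammar(corpora[[r]], k, pseudo_count, source_name = r))
  ratios <- matrix(NA_real_, length(nm), length(nm),
                   dimnames = list(source = nm, target = nm))
  for (i in seq_along(nm)) for (j in seq_along(nm))
    ratios[i, j] <- encoded_length(grammars[[i]], corpora[[j]])$ratio
  pct <- sweep(ratios, 2L, diag(ratios), function(r, d) 100 * (r - d) / d)
  structure(list(ratios = ratios, percent_increase = pct, k = k,
                 pseudo_count = pseudo_count),
            class = "cross_compression")
}

#' @export
print.cross_compression <- function(x, ...) {
  cat("<cross_compression> k =", x$k, "\nratios (source x target):\n")
  print(round(x$ratios, 4))
  cat("percent increase over target self-compression:\n")
  print(round(x$percent_increase, 2))
  invisible(x)
}
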