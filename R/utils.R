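DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a run seed
#'
#' One top-level seed drives a whole pipeline run; each stage gets its own
#' deterministic sub-seed so stages can be re-run in isolation.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name.
#' @return An integer seed, always in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% (2^31 - 1))
}

#' Enumerate all k-mers in lexicographic order
#'
#' @param k Word length (>= 1).
#' @return Character vector of `4^k` k-mers over A,C,G,T, lexicographically
#'   sorted (A < C < G < T, leftmost position most significant).
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1)
  km <- DNA_BASES
  if (k > 1) {
    for (i in seq_len(k - 1L)) {
      km <- as.vector(t(outer(km, DNA_BASES, paste0)))
    }
  }
  km
}

# Overlapping k-mer counts of one sequence, in all_kmers(k) order.
# Windows containing characters outside A,C,G,T (e.g. N) are skipped.
count_kmers_one <- function(seq, k, kmers = all_kmers(k)) {
  L <- nchar(seq)
  if (L < k) stop("sequence shorter than k (", L, " < ", k, ")")
  starts <- seq_len(L - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  words <- words[!grepl("[^ACGT]", words)]
  tab <- tabulate(factor(words, levels = kmers), nbins = length(kmers))
  names(tab) <- kmers
  tab
}

# Count (possibly overlapping) occurrences of a fixed motif in a sequence.
count_motif <- function(seq, motif) {
  if (!nzchar(motif)) stop("motif must be non-empty")
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (length(hits) == 1L && hits[1] == -1L) 0L else length(hits)
}

# Upper-case, U -> T. Validates alphabet {A,C,G,T,N} unless check = FALSE.
normalize_sequence <- function(seq, check = TRUE, what = "sequence") {
  s <- chartr("u", "t", seq)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  if (check && any(grepl("[^ACGTN]", s))) {
    bad <- which(grepl("[^ACGTN]", s))[1]
    stop("invalid character in ", what, " (record ", bad,
         "): only A,C,G,T,U,N allowed")
  }
  s
}

# Sample n values from a discrete distribution given as a named prob vector.
sample_discrete <- function(values, probs, n) {
  values[sample.int(length(values), n, replace = TRUE, prob = probs)]
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

is_fraction <- function(x, open = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
}
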