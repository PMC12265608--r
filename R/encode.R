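#' Six-track encoding of a transcript
#'
#' Produces the 6 x L integer matrix used as model input in splice-aware
#' sequence models: rows 1-4 one-hot encode A, C, G, T (an N column is
#' all-zero there); row 5 marks the first nucleotide of each exon (the
#' splice track); row 6 marks the first nucleotide of each codon inside the
#' CDS (the codon/reading-frame track). All positions are transcript
#' coordinates.
#'
#' @param t A [transcript()].
#' @return Integer matrix with rownames
#'   `c("A","C","G","T","splice","codon")` and one column per nucleotide.
#' @examples
#' six_track_encode(transcript("tx", "ATGATG", cds = c(0, 6)))
#' @export
six_track_encode <- function(t) {
  validate_transcript(t)
  L <- nchar(t$sequence)
  m <- matrix(0L, nrow = 6L, ncol = L,
              dimnames = list(c(DNA_BASES, "splice", "codon"), NULL))
  chars <- strsplit(t$sequence, "")[[1]]
  for (b in seq_along(DNA_BASES)) m[b, chars == DNA_BASES[b]] <- 1L
  m["splice", t$exon_starts + 1L] <- 1L
  if (!is.null(t$cds)) {
    starts <- seq.int(t$cds[1], t$cds[2] - 1L, by = 3L)
    m["codon", starts + 1L] <- 1L
  }
  m
}

#' Split a sequence into bounded-length chunks
#'
#' Used when an embedding model's context window is shorter than the
#' transcript: the sequence is cut into windows of at most `max_len`
#' nucleotides taken every `max_len - overlap` positions. With
#' `overlap = 0` the chunks partition the sequence exactly; with positive
#' overlap, dropping the first `overlap` characters of every chunk after
#' the first restores the original sequence.
#'
#' @param seq Character scalar.
#' @param max_len Maximum chunk length (positive integer).
#' @param overlap Number of positions shared between consecutive chunks;
#'   must be strictly smaller than `max_len`.
#' @return Character vector of chunks, 5' to 3'; the integer start offsets
#'   (0-based) are attached as attribute `"starts"`.
#' @export
chunk_sequence <- function(seq, max_len, overlap = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is_count(max_len)) stop("max_len must be a positive integer")
  if (!is_count(overlap, min = 0)) stop("overlap must be a non-negative integer")
  if (overlap >= max_len) stop("overlap must be smaller than max_len")
  L <- nchar(seq)
  if (L == 0L) return(character(0))
  stride <- max_len - overlap
  starts <- seq.int(0L, L - 1L, by = stride)
  chunks <- substring(seq, starts + 1L, pmin(starts + max_len, L))
  attr(chunks, "starts") <- as.integer(starts)
  chunks
}
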