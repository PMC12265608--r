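#' Detect upstream AUGs in a 5'UTR
#'
#' Scans the UTR (which must exclude the main start codon itself) for
#' `ATG` in all three frames; uAUGs typically suppress translation of the
#' main open reading frame.
#'
#' @param utr_seq 5'UTR sequence, 5' to 3', upstream of the main start.
#' @return List `has_uaug` (logical), `count` (integer; occurrences at
#'   distinct start offsets).
#' @export
detect_uaug <- function(utr_seq) {
  utr_seq <- normalize_sequence(utr_seq, check = FALSE)
  n <- count_motif(utr_seq, "ATG")
  list(has_uaug = n > 0L, count = as.integer(n))
}

#' Classify Kozak context strength
#'
#' Operates on the 10-nt window covering positions -6..+4 around the main
#' start codon (the A of the AUG at +1; there is no position 0). The
#' consensus positions that matter most are -3 and +4: the context is
#' called `"strong"` iff the base at -3 is a purine (A or G) *and* the
#' base at +4 is G; anything else is `"weak"`.
#'
#' @param context 10-nt window `-6..-1, +1..+4`.
#' @return `"strong"` or `"weak"`.
#' @examples
#' kozak_strength("GCCACCATGG")  # strong
#' kozak_strength("GCCTCCATGC")  # weak
#' @export
kozak_strength <- function(context) {
  context <- normalize_sequence(context, check = FALSE)
  if (nchar(context) != 10L)
    stop("context must be the 10-nt window -6..+4 (got ", nchar(context),
         " nt)")
  minus3 <- substr(context, 4L, 4L)
  plus4 <- substr(context, 10L, 10L)
  if (minus3 %in% c("A", "G") && plus4 == "G") "strong" else "weak"
}

#' Annotate a transcript's UTR features for the compositional design
#'
#' Convenience wrapper: given the full sequence and the 0-based offset of
#' the main start codon, extracts the 5'UTR and the -6..+4 Kozak window
#' and returns the two design features.
#'
#' @param sequence Full transcript sequence.
#' @param cds_start 0-based offset of the main AUG.
#' @return Data frame row: `has_uaug`, `uaug_count`, `kozak`.
#' @export
annotate_utr <- function(sequence, cds_start) {
  sequence <- normalize_sequence(sequence, check = FALSE)
  if (cds_start < 6L || nchar(sequence) < cds_start + 7L)
    stop("need >= 6 nt upstream and >= 4 nt downstream of the start codon")
  utr <- substr(sequence, 1L, cds_start)
  window <- paste0(substr(sequence, cds_start - 5L, cds_start),
                   substr(sequence, cds_start + 1L, cds_start + 4L))
  ua <- detect_uaug(utr)
  data.frame(has_uaug = ua$has_uaug, uaug_count = ua$count,
             kozak = kozak_strength(window))
}

#' Build the compositional-generalization split
#'
#' Train on three of the four Kozak x uAUG cells — (strong, no uAUG),
#' (weak, no uAUG), (strong, uAUG) — and test exclusively on the cell
#' never seen in training: weak Kozak *with* a uAUG. A model that has
#' learned the two regulatory elements' individual effects must recombine
#' them to predict the held-out cell.
#'
#' @param annotated Data frame with columns `id`, `has_uaug` (logical or
#'   0/1) and `kozak` (`"strong"`/`"weak"`).
#' @return A [split_assignment()] (strategy `"compositional"`); no record
#'   is discarded. Errors if the test cell is empty.
#' @export
build_compositional_split <- function(annotated) {
  need <- c("id", "has_uaug", "kozak")
  if (!all(need %in% names(annotated)))
    stop("annotated must have columns ", paste(need, collapse = ", "))
  ua <- as.logical(annotated$has_uaug)
  weak <- annotated$kozak == "weak"
  in_test <- ua & weak
  if (!any(in_test))
    stop("empty test cell: no (weak Kozak, uAUG) record")
  cells <- table(kozak = annotated$kozak, uaug = ua)
  if (any(cells == 0))
    warning("not all four Kozak x uAUG cells are populated")
  assign <- setNames(ifelse(in_test, "test", "train"), annotated$id)
  split_assignment(assign, "compositional", NA_integer_,
                   list(test_cell = "weak_kozak_with_uaug"))
}

#' Percent performance drop under the compositional split
#'
#' For each model, `100 * (random - compositional) / random`: the share of
#' random-split performance lost when the evaluated combination of
#' regulatory elements was never seen in training. Models with
#' non-positive random scores are excluded with a warning.
#'
#' @param comp_scores,random_scores Named numeric vectors (per model) of
#'   the test metric under the compositional and random splits.
#' @return List `per_model` (named percent vector), `average`.
#' @export
compositional_drop <- function(comp_scores, random_scores) {
  common <- intersect(names(comp_scores), names(random_scores))
  if (!length(common)) stop("no matching models")
  r <- random_scores[common]; cmp <- comp_scores[common]
  ok <- r > 0
  if (any(!ok))
    warning("excluding model(s) with non-positive random score: ",
            paste(common[!ok], collapse = ", "))
  pct <- 100 * (r[ok] - cmp[ok]) / r[ok]
  list(per_model = pct, average = mean(pct))
}
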