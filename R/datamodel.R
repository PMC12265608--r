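#' Construct a transcript record
#'
#' A transcript is a mature mRNA: the spliced, exon-only sequence read 5'
#' to 3'. Coordinates are transcript-relative, 0-based, half-open. The splice
#' structure is carried as the offsets of the first nucleotide of each exon;
#' the coding region (if any) as a `[start, end)` interval whose length must
#' be a whole number of codons.
#'
#' @param id Transcript identifier (unique within a dataset).
#' @param sequence Nucleotide string over A,C,G,T,U,N (any case; U and
#'   lower case are normalized to the canonical upper-case T alphabet).
#' @param gene_id Gene the transcript belongs to; defaults to `id`. Splitting
#'   operates at gene granularity so all isoforms of a gene travel together.
#' @param chromosome Chromosome name, or `NA` if unknown.
#' @param exon_starts Integer vector of 0-based transcript offsets of each
#'   exon's first nucleotide; strictly increasing, starting at 0.
#' @param cds Length-2 numeric `c(start, end)`, 0-based half-open, or `NULL`
#'   for non-coding transcripts. `end - start` must be divisible by 3.
#' @return An object of class `"transcript"`.
#' @examples
#' tx <- transcript("tx1", "ATGGCCTAA", cds = c(0, 9))
#' @export
transcript <- function(id, sequence, gene_id = id, chromosome = NA_character_,
                       exon_starts = 0L, cds = NULL) {
  sequence <- normalize_sequence(sequence, what = paste0("transcript ", id))
  obj <- structure(
    list(id = as.character(id), gene_id = as.character(gene_id),
         chromosome = as.character(chromosome), sequence = sequence,
         exon_starts = as.integer(exon_starts),
         cds = if (is.null(cds)) NULL else as.integer(cds)),
    class = "transcript")
  validate_transcript(obj)
  obj
}

#' Validate a transcript's structural invariants
#'
#' @param t A `"transcript"` object.
#' @return `t`, invisibly; errors describe the violated invariant.
#' @export
validate_transcript <- function(t) {
  stopifnot(inherits(t, "transcript"))
  L <- nchar(t$sequence)
  es <- t$exon_starts
  if (length(es) < 1L || es[1] != 0L)
    stop("transcript ", t$id, ": first exon_start must be 0")
  if (any(es < 0L) || any(es >= L))
    stop("transcript ", t$id, ": exon_starts must lie in [0, length)")
  if (length(es) > 1L && any(diff(es) <= 0L))
    stop("transcript ", t$id, ": exon_starts must be strictly increasing")
  if (!is.null(t$cds)) {
    if (length(t$cds) != 2L)
      stop("transcript ", t$id, ": cds must be c(start, end)")
    if (t$cds[1] < 0L || t$cds[1] >= t$cds[2] || t$cds[2] > L)
      stop("transcript ", t$id, ": cds must satisfy 0 <= start < end <= length")
    if ((t$cds[2] - t$cds[1]) %% 3L != 0L)
      stop("transcript ", t$id, ": cds length must be a multiple of 3")
  }
  invisible(t)
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript> ", x$id, " (gene ", x$gene_id, ", ",
      ifelse(is.na(x$chromosome), "chrom ?", x$chromosome), ")\n", sep = "")
  cat("  length ", nchar(x$sequence), " nt, ", length(x$exon_starts),
      " exon(s), ",
      if (is.null(x$cds)) "non-coding"
      else paste0("CDS [", x$cds[1], ", ", x$cds[2], ")"), "\n", sep = "")
  invisible(x)
}

#' Describe a prediction task
#'
#' Tasks are categorized by label kind and by *locality*: global tasks carry
#' transcript-level labels (e.g. half-life, ribosome load, localization),
#' local tasks arise from nucleotide-level context (e.g. RBP binding,
#' variant effect). The metric is tied to the kind: Pearson r for
#' regression, area under the precision-recall curve for binary tasks, and
#' mean AUPRC across labels for multilabel tasks.
#'
#' @param name Task name.
#' @param kind `"regression"`, `"binary"` or `"multilabel"`.
#' @param metric `"pearson_r"`, `"auprc"` or `"mean_auprc"`; defaults to the
#'   metric implied by `kind`.
#' @param locality `"global"` or `"local"`.
#' @return An object of class `"task_spec"`.
#' @export
task_spec <- function(name, kind, metric = NULL, locality = "global") {
  kind <- match.arg(kind, c("regression", "binary", "multilabel"))
  implied <- c(regression = "pearson_r", binary = "auprc",
               multilabel = "mean_auprc")[[kind]]
  metric <- metric %||% implied
  if (metric != implied)
    stop("metric '", metric, "' incompatible with kind '", kind,
         "' (expected '", implied, "')")
  locality <- match.arg(locality, c("global", "local"))
  structure(list(name = name, kind = kind, metric = metric,
                 locality = locality), class = "task_spec")
}

#' Bundle transcripts with a label table and task description
#'
#' @param transcripts List of [transcript()] objects.
#' @param labels Data frame with one row per labelled transcript; must have
#'   an `id` column, remaining columns are subtask labels.
#' @param task A [task_spec()].
#' @return An object of class `"labeled_dataset"` with elements
#'   `transcripts`, `labels`, `task`.
#' @export
labeled_dataset <- function(transcripts, labels, task) {
  stopifnot(inherits(task, "task_spec"), is.data.frame(labels))
  if (!"id" %in% names(labels)) stop("labels must have an 'id' column")
  ids <- vapply(transcripts, function(t) t$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate transcript ids")
  if (anyDuplicated(labels$id)) stop("duplicate ids in label table")
  missing <- setdiff(labels$id, ids)
  if (length(missing))
    stop("labelled ids absent from transcripts: ",
         paste(head(missing, 3), collapse = ", "))
  value_cols <- setdiff(names(labels), "id")
  if (task$kind == "multilabel") {
    for (cl in value_cols) {
      v <- labels[[cl]]
      if (!all(v %in% c(0, 1)))
        stop("multilabel column '", cl, "' must be 0/1")
    }
  }
  structure(list(transcripts = transcripts, labels = labels, task = task),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", length(x$transcripts), " transcripts, ",
      nrow(x$labels), " labelled, task '", x$task$name, "' (",
      x$task$kind, "/", x$task$locality, ")\n", sep = "")
  invisible(x)
}

#' Record a train/test partition with its provenance
#'
#' @param assignment Named character vector mapping every id to `"train"`,
#'   `"test"` or `"val"`.
#' @param strategy Name of the splitting strategy that produced it.
#' @param seed Seed used (or `NA` for deterministic strategies).
#' @param params Named list of strategy parameters, kept for provenance.
#' @return An object of class `"split_assignment"`.
#' @export
split_assignment <- function(assignment, strategy, seed = NA_integer_,
                             params = list()) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be a fully named vector")
  if (anyDuplicated(names(assignment)))
    stop("duplicate ids in split assignment")
  bad <- setdiff(unique(assignment), c("train", "test", "val"))
  if (length(bad))
    stop("invalid partition label(s): ", paste(bad, collapse = ", "))
  structure(list(assignment = assignment, strategy = strategy,
                 seed = seed, params = params),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  tab <- table(factor(x$assignment, levels = c("train", "val", "test")))
  cat("<split_assignment> strategy '", x$strategy, "', seed ",
      x$seed, "\n  ", paste(names(tab), tab, sep = ": ", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Ids assigned to one side of a split
#'
#' @param split A [split_assignment()].
#' @param side `"train"`, `"test"` or `"val"`.
#' @return Character vector of ids.
#' @export
split_ids <- function(split, side) {
  stopifnot(inherits(split, "split_assignment"))
  side <- match.arg(side, c("train", "test", "val"))
  names(split$assignment)[split$assignment == side]
}

#' Wrap an id-keyed embedding matrix
#'
#' @param ids Character vector of row identities.
#' @param values Numeric matrix, one row per id, fixed dimensionality.
#' @return An object of class `"embedding_matrix"` (list with `ids`,
#'   `values`; `values` carries `ids` as rownames).
#' @export
embedding_matrix <- function(ids, values) {
  values <- as.matrix(values)
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) stop("one id per row required")
  if (anyDuplicated(ids)) stop("duplicate ids in embedding matrix")
  if (!all(is.finite(values))) stop("non-finite embedding values")
  rownames(values) <- ids
  structure(list(ids = ids, values = values), class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("<embedding_matrix> ", nrow(x$values), " x ", ncol(x$values), "\n",
      sep = "")
  invisible(x)
}
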