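#' Read transcripts from a FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the
#' transcript id; optional `key=value` pairs in the remainder of the header
#' are recognized for `gene=`, `chrom=`, `exon_starts=` (comma-separated)
#' and `cds=` (`start-end`, 0-based half-open). Sequences are upper-cased
#' and U is normalized to T on load.
#'
#' @param path Path to a FASTA file.
#' @return List of [transcript()] objects, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(list())
  lines <- readLines(path, n = 50L, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first) && !startsWith(trimws(lines[first]), ">"))
    stop("malformed FASTA at line ", first, ": expected '>' header")
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate transcript id in FASTA: ",
         ids[which(duplicated(ids))[1]])
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    kv <- parse_header_kv(headers[i])
    seq_i <- as.character(set[[i]])
    es <- if (!is.null(kv$exon_starts))
      as.integer(strsplit(kv$exon_starts, ",")[[1]]) else 0L
    cds <- if (!is.null(kv$cds)) {
      parts <- as.integer(strsplit(kv$cds, "-")[[1]])
      if (length(parts) != 2L || anyNA(parts))
        stop("bad cds field in header of ", ids[i])
      parts
    } else NULL
    out[[i]] <- transcript(
      id = ids[i], sequence = seq_i,
      gene_id = kv$gene %||% ids[i],
      chromosome = kv$chrom %||% NA_character_,
      exon_starts = es, cds = cds)
  }
  out
}

parse_header_kv <- function(header) {
  toks <- strsplit(header, "\\s+")[[1]][-1]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  if (!length(toks)) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, character(1), 1L))
}

#' Write transcripts to a FASTA file
#'
#' Inverse of [read_fasta()]: gene, chromosome, exon structure and CDS are
#' serialized as `key=value` pairs on the header so a round-trip preserves
#' the full record.
#'
#' @param transcripts List of [transcript()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path) {
  headers <- vapply(transcripts, function(t) {
    h <- paste0(t$id, " gene=", t$gene_id)
    if (!is.na(t$chromosome)) h <- paste0(h, " chrom=", t$chromosome)
    h <- paste0(h, " exon_starts=", paste(t$exon_starts, collapse = ","))
    if (!is.null(t$cds)) h <- paste0(h, " cds=", t$cds[1], "-", t$cds[2])
    h
  }, character(1))
  seqs <- vapply(transcripts, `[[`, character(1), "sequence")
  set <- Biostrings::BStringSet(setNames(seqs, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a delimited label table
#'
#' Expects a header row whose first column is the transcript id (named
#' `id`); every other column is a subtask label. Tab- and comma-delimited
#' files are both accepted (sniffed from the header line). Lines starting
#' with `#` are treated as comments.
#'
#' @param path Path to a TSV/CSV file.
#' @param task A [task_spec()]; label values are validated against its kind.
#' @return Data frame with an `id` column plus numeric label columns.
#' @export
read_label_table <- function(path, task) {
  stopifnot(inherits(task, "task_spec"))
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 25L, warn = FALSE)
  hdr <- hdr[!startsWith(hdr, "#")][1]
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  if (names(df)[1] != "id")
    stop("schema error: first column must be 'id', got '", names(df)[1], "'")
  if (nrow(df) == 0L) {
    out <- df
    out[-1] <- lapply(out[-1], as.numeric)
    return(out)
  }
  for (cl in setdiff(names(df), "id")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (anyNA(v) & !anyNA(df[[cl]])) {
      row <- which(is.na(v))[1]
      stop("non-numeric label in column '", cl, "', row ", row,
           " (value '", df[[cl]][row], "')")
    }
    if (task$kind %in% c("binary", "multilabel") && !all(v %in% c(0, 1)))
      stop("column '", cl, "' must be 0/1 for ", task$kind, " tasks (row ",
           which(!v %in% c(0, 1))[1], ")")
    df[[cl]] <- v
  }
  df
}

#' Serialize a split assignment as TSV
#'
#' Columns: `id`, `split`, `strategy`, `seed`; provenance (strategy
#' parameters) is recorded in `#`-prefixed comment lines.
#'
#' @param split A [split_assignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_tsv <- function(split, path) {
  stopifnot(inherits(split, "split_assignment"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(split$params)) {
    writeLines(paste0("# params: ",
                      paste(names(split$params),
                            vapply(split$params, function(p)
                              paste(format(p), collapse = ","), character(1)),
                            sep = "=", collapse = " ")), con)
  }
  df <- data.frame(id = names(split$assignment),
                   split = unname(split$assignment),
                   strategy = split$strategy, seed = split$seed)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a split assignment written by [write_split_tsv()]
#'
#' @param path Path to the TSV.
#' @return A [split_assignment()].
#' @export
read_split_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  split_assignment(setNames(df$split, df$id),
                   strategy = df$strategy[1], seed = df$seed[1])
}

#' Read a paralog edge list
#'
#' @param path TSV with columns `gene_a`, `gene_b` and optionally
#'   `identity` (fraction in `[0, 1]`).
#' @return Data frame of class `"paralog_edges"`.
#' @export
read_paralog_edges <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  paralog_edges(df)
}

#' Construct/validate a paralog edge table
#'
#' @param df Data frame with `gene_a`, `gene_b`, optional `identity`.
#' @return The validated data frame, classed `"paralog_edges"`.
#' @export
paralog_edges <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("edge table needs columns gene_a, gene_b")
  if (nrow(df) && any(df$gene_a == df$gene_b))
    stop("self-edge in paralog table (gene_a == gene_b)")
  if ("identity" %in% names(df) && nrow(df)) {
    if (any(df$identity < 0 | df$identity > 1, na.rm = TRUE))
      stop("identity must lie in [0, 1]")
  }
  class(df) <- c("paralog_edges", "data.frame")
  df
}
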