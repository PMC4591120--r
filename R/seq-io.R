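#' Read a FASTA file with strict validation
#'
#' Wraps [Biostrings::readBStringSet()] and enforces the conventions the rest
#' of the pipeline relies on: unique record ids (first whitespace-delimited
#' word of the header), non-empty sequences, and a restricted alphabet
#' (A,C,G,T plus N for nucleotide input; the amino-acid alphabet plus X and
#' `*` for protein input). Sequences are stored uppercase.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` for nucleotide, `"aa"` for protein.
#' @return A [Biostrings::DNAStringSet] (`"nt"`) or [Biostrings::AAStringSet]
#'   (`"aa"`) named by record id, with a `description` metadata column
#'   holding the remainder of each header line.
#' @export
readFasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1], " in ", path)
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id ", ids[which(nchar(seqs) == 0L)[1]],
         " in ", path)
  }
  allowed <- if (alphabet == "nt") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX*"
  bad <- grepl(sprintf("[^%s]", gsub("\\*", "\\\\*", allowed)), seqs)
  if (any(bad)) {
    b <- which(bad)[1]
    bad_char <- regmatches(seqs[b], regexpr(
      sprintf("[^%s]", gsub("\\*", "\\\\*", allowed)), seqs[b]))
    ## locate the offending line for the error message
    lines <- readLines(path, warn = FALSE)
    ln <- which(grepl(bad_char, toupper(lines), fixed = TRUE) &
                  !startsWith(lines, ">"))
    stop(sprintf(
      "invalid character '%s' for alphabet '%s' in record '%s' (line %s)",
      bad_char, alphabet, ids[b], if (length(ln)) ln[1] else "?"))
  }
  out <- if (alphabet == "nt") Biostrings::DNAStringSet(seqs)
    else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::metadata(out)$description <- stats::setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param x A named XStringSet or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path, width = 70L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

.HIT_COLS <- c("qid", "sid", "pident", "aln_len", "mismatches", "gapopens",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")
.HIT_NUMERIC <- .HIT_COLS[3:12]

#' Read a 12-column tabular similarity hit file
#'
#' The classical 12-column tab-separated pairwise-search layout: query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, E-value, bit score. Lines starting
#' with `#` are skipped. Rows with a column count other than 12, or
#' non-numeric values in numeric columns, are hard errors reported with
#' their line number. Query coordinates may run backwards (qstart > qend),
#' indicating a minus-strand/frame hit.
#'
#' @param path Path to the hit table.
#' @return A data.frame with columns qid, sid, pident, aln_len, mismatches,
#'   gapopens, qstart, qend, sstart, send, evalue, bitscore.
#' @export
readHits <- function(path) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 2), .HIT_COLS[1:2]))
    for (cc in .HIT_NUMERIC) out[[cc]] <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    b <- which(nf != 12L)[1]
    stop(sprintf("hit row at line %d has %d columns (12 required)",
                 lineno[b], nf[b]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  out <- data.frame(qid = m[, 1], sid = m[, 2], stringsAsFactors = FALSE)
  for (k in 3:12) {
    v <- suppressWarnings(as.numeric(m[, k]))
    bad <- which(is.na(v) & !(toupper(m[, k]) %in% "NA"))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column %s at line %d",
                   m[bad[1], k], .HIT_COLS[k], lineno[bad[1]]))
    }
    out[[.HIT_COLS[k]]] <- v
  }
  int_cols <- c("aln_len", "mismatches", "gapopens",
                "qstart", "qend", "sstart", "send")
  for (cc in int_cols) out[[cc]] <- as.integer(out[[cc]])
  if (any(out$pident < 0 | out$pident > 100))
    stop("pident outside [0, 100] in ", path)
  if (any(out$aln_len < 1L)) stop("non-positive alignment length in ", path)
  if (any(out$evalue < 0)) stop("negative E-value in ", path)
  out
}

#' Write a hit table in the 12-column layout
#' @param hits Data.frame as returned by [readHits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  missing <- setdiff(.HIT_COLS, names(hits))
  if (length(missing)) stop("missing hit columns: ",
                            paste(missing, collapse = ", "))
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write records as a TSV report with a header row
#'
#' Floating-point values are rendered with a configurable number of
#' significant digits (default 6) so written tables round-trip at that
#' precision.
#'
#' @param records Data.frame (or coercible).
#' @param path Output path.
#' @param schema Character vector of column names to write, in order.
#'   Defaults to all columns.
#' @param digits Significant digits for numeric columns.
#' @return `path`, invisibly.
#' @export
writeTable <- function(records, path, schema = NULL, digits = 6L) {
  records <- as.data.frame(records)
  if (is.null(schema)) schema <- names(records)
  missing <- setdiff(schema, names(records))
  if (length(missing)) stop("records lack schema field(s): ",
                            paste(missing, collapse = ", "))
  out <- records[, schema, drop = FALSE]
  for (cc in schema) {
    if (is.double(out[[cc]])) out[[cc]] <- signif(out[[cc]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV report written by [writeTable()]
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
readTable <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read / write one-value-per-line Ks lists
#'
#' @param path File path. Blank lines and `#` comments are skipped on read.
#' @return Numeric vector of Ks values.
#' @export
readKsList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  v <- suppressWarnings(as.numeric(lines))
  if (anyNA(v)) stop("non-numeric Ks value: '", lines[which(is.na(v))[1]],
                     "' in ", path)
  v
}

#' @rdname readKsList
#' @param values Numeric vector to write.
#' @param digits Significant digits.
#' @export
writeKsList <- function(values, path, digits = 6L) {
  writeLines(format(signif(values, digits), trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}
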