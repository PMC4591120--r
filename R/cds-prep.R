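#' Extract coding regions guided by best protein hits
#'
#' For each unigene with a best hit, the query span of the hit
#' (\code{[min(qstart,qend), max(qstart,qend)]}) is taken as the coding
#' region; a hit with qstart > qend indicates a minus-strand match and the
#' span is reverse-complemented. The span is trimmed at its 3' end to a
#' multiple of three, translated with the standard genetic code (codons
#' containing N translate to X), and quality-filtered: regions shorter than
#' 50 codons are rejected (`too_short`), as are translations with an internal
#' stop codon (`internal_stop`). A terminal stop codon is trimmed before the
#' internal-stop test (a natural ORF end is not a quality defect) and before
#' the length rule is applied.
#'
#' @param unigenes Named [Biostrings::DNAStringSet] of unigene sequences.
#' @param hits One-hit-per-query data.frame ([bestHits()] output); qid must
#'   be present in `unigenes`.
#' @return A list with `cds` (DNAStringSet, in-frame coding sequences),
#'   `proteins` (AAStringSet, their translations), `info` (data.frame: id,
#'   frame, n_codons) and `rejects` (data.frame: id, reason).
#' @export
extractCds <- function(unigenes, hits) {
  if (anyDuplicated(hits$qid)) stop("multiple hits per query; run bestHits()")
  miss <- setdiff(hits$qid, names(unigenes))
  if (length(miss)) stop("hit query id not in unigene set: ", miss[1])
  cds_list <- character(0); prot_list <- character(0)
  info <- list(); rejects <- list()
  for (k in seq_len(nrow(hits))) {
    id <- hits$qid[k]
    qs <- hits$qstart[k]; qe <- hits$qend[k]
    minus <- qs > qe
    lo <- min(qs, qe); hi <- max(qs, qe)
    if (lo < 1L || hi > length(unigenes[[id]])) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = id, reason = "span_outside_sequence")
      next
    }
    span <- Biostrings::subseq(unigenes[[id]], start = lo, end = hi)
    if (minus) span <- Biostrings::reverseComplement(span)
    keep_nt <- 3L * (length(span) %/% 3L)
    if (keep_nt < 150L) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = id, reason = "too_short")
      next
    }
    span <- Biostrings::subseq(span, 1L, keep_nt)
    prot <- as.character(Biostrings::translate(
      span, if.fuzzy.codon = "X", no.init.codon = TRUE))
    ## trim a natural terminal stop together with its codon
    if (endsWith(prot, "*")) {
      prot <- substr(prot, 1L, nchar(prot) - 1L)
      span <- Biostrings::subseq(span, 1L, length(span) - 3L)
    }
    if (nchar(prot) < 50L) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = id, reason = "too_short")
      next
    }
    if (grepl("*", prot, fixed = TRUE)) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        id = id, reason = "internal_stop")
      next
    }
    frame <- (if (minus) -1L else 1L) * (((lo - 1L) %% 3L) + 1L)
    cds_list[id] <- as.character(span)
    prot_list[id] <- prot
    info[[length(info) + 1L]] <- data.frame(
      id = id, frame = frame, n_codons = nchar(prot))
  }
  list(
    cds = Biostrings::DNAStringSet(cds_list),
    proteins = Biostrings::AAStringSet(prot_list),
    info = if (length(info)) do.call(rbind, info)
      else data.frame(id = character(0), frame = integer(0),
                      n_codons = integer(0)),
    rejects = if (length(rejects)) do.call(rbind, rejects)
      else data.frame(id = character(0), reason = character(0)))
}

#' Protein quality filter
#'
#' Keeps proteins that are at least 50 residues long and contain no internal
#' stop codon. A single terminal `*` is trimmed before either rule is
#' applied.
#'
#' @param proteins Named [Biostrings::AAStringSet] or named character vector.
#' @param min_aa Minimum length in residues (strict: shorter is rejected,
#'   exactly `min_aa` is kept).
#' @return List with `accepted` (AAStringSet) and `rejects` (data.frame: id,
#'   reason in `too_short` / `internal_stop`).
#' @export
filterProteins <- function(proteins, min_aa = 50L) {
  seqs <- as.character(proteins)
  ids <- names(proteins)
  if (is.null(ids)) stop("proteins must be named")
  trimmed <- ifelse(endsWith(seqs, "*"), substr(seqs, 1L, nchar(seqs) - 1L),
                    seqs)
  internal <- grepl("*", trimmed, fixed = TRUE)
  short <- nchar(trimmed) < min_aa
  reason <- ifelse(short, "too_short",
                   ifelse(internal, "internal_stop", NA_character_))
  keep <- is.na(reason)
  accepted <- Biostrings::AAStringSet(stats::setNames(trimmed[keep],
                                                      ids[keep]))
  rejects <- data.frame(id = ids[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(accepted = accepted, rejects = rejects)
}
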