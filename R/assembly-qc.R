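#' Assembly length statistics
#'
#' Computes the usual de novo assembly summary: sequence count, total bases,
#' mean length, N50, AT content and a length histogram. N50 is the length of
#' the sequence at which the cumulative length of all sequences, taken in
#' decreasing length order, first reaches half of the total assembled bases.
#' AT content is (A+T)/(A+C+G+T); N bases are excluded from the denominator.
#'
#' @param records A [Biostrings::DNAStringSet] (e.g. from [readFasta()]).
#' @param bin_width Histogram bin width in bases.
#' @param bin_range Closed-below range covered by regular bins; lengths below
#'   the range go into a leading bin and lengths at/above its top into an
#'   open-ended last bin, so histogram counts always sum to the number of
#'   sequences.
#' @return A list of class `ksd_length_stats` with elements `n_seqs`,
#'   `total_bases`, `mean_len`, `n50`, `at_content` and `histogram`
#'   (data.frame: bin_low, bin_high, count; bin_high is NA for the
#'   open-ended bin).
#' @export
lengthStats <- function(records, bin_width = 100L, bin_range = c(200L, 3000L)) {
  if (length(records) == 0L) stop("lengthStats: empty sequence set")
  len <- Biostrings::width(records)
  total <- sum(as.numeric(len))
  srt <- sort(len, decreasing = TRUE)
  n50 <- srt[which(cumsum(as.numeric(srt)) >= total / 2)[1]]
  freq <- Biostrings::letterFrequency(records, letters = c("A", "C", "G", "T"))
  acgt <- colSums(freq)
  at <- (acgt[["A"]] + acgt[["T"]]) / sum(acgt)

  lows <- seq(bin_range[1], bin_range[2] - bin_width, by = bin_width)
  breaks <- c(-Inf, lows, bin_range[2], Inf)
  counts <- as.integer(table(cut(len, breaks = breaks, right = FALSE)))
  hist <- data.frame(
    bin_low = c(0L, lows, bin_range[2]),
    bin_high = c(lows, bin_range[2], NA_integer_),
    count = counts)
  ## drop the leading catch-all bin if nothing falls below the range
  if (hist$count[1] == 0L) hist <- hist[-1, , drop = FALSE]
  rownames(hist) <- NULL
  structure(list(n_seqs = length(records), total_bases = total,
                 mean_len = total / length(records), n50 = n50,
                 at_content = unname(at), histogram = hist),
            class = "ksd_length_stats")
}

#' @export
print.ksd_length_stats <- function(x, ...) {
  cat(sprintf(
    "Assembly: %d sequences, %.0f bases (mean %.1f bp, N50 %d bp, AT %.1f%%)\n",
    x$n_seqs, x$total_bases, x$mean_len, x$n50, 100 * x$at_content))
  invisible(x)
}

#' Sequencing coverage depth
#'
#' Fold coverage computed by dividing the number of nucleotides in the
#' cleaned reads by the number of nucleotides in the assembled unigenes.
#'
#' @param cleaned_read_bases Total bases in the cleaned read set.
#' @param unigene_bases Total bases in the unigene set.
#' @return Fold coverage (numeric).
#' @export
coverageDepth <- function(cleaned_read_bases, unigene_bases) {
  if (unigene_bases <= 0) stop("unigene_bases must be > 0")
  if (cleaned_read_bases <= 0) stop("cleaned_read_bases must be > 0")
  cleaned_read_bases / unigene_bases
}

#' Best hit per query
#'
#' Selects, per query, the hit with the highest bit score (default) or the
#' smallest E-value. Ties are broken by smaller E-value (resp. higher bit
#' score), then by lexicographically smallest subject id, so the result is
#' deterministic.
#'
#' @param hits Hit data.frame from [readHits()].
#' @param rule `"bitscore"` or `"evalue"`.
#' @return One-row-per-query data.frame (same columns as `hits`).
#' @export
bestHits <- function(hits, rule = c("bitscore", "evalue")) {
  rule <- match.arg(rule)
  if (nrow(hits) == 0L) return(hits)
  ord <- if (rule == "bitscore") {
    order(hits$qid, -hits$bitscore, hits$evalue, hits$sid)
  } else {
    order(hits$qid, hits$evalue, -hits$bitscore, hits$sid)
  }
  h <- hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$qid), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Ortholog Hit Ratio (OHR)
#'
#' Transcript completeness relative to the best-matched protein: the number
#' of query bases in the hit region divided by three times the length of the
#' best-matched protein. OHR >= 1 indicates the assembled transcript covers
#' the entire matched protein.
#'
#' @param best One-hit-per-query data.frame (see [bestHits()]).
#' @param protein_lengths Named integer vector: protein id -> length in
#'   residues.
#' @param bin_width Width of the disjoint OHR bins in the summary.
#' @return A list with `records` (data.frame: qid, sid, hit_bases,
#'   protein_len, ohr), `classes` (cumulative counts: full_length = OHR >= 1,
#'   over_0.75 = OHR > 0.75, over_0.5 = OHR > 0.5, n) and `bins`
#'   (disjoint bins of width `bin_width`; the last bin collects OHR >= 1).
#' @export
orthologHitRatio <- function(best, protein_lengths, bin_width = 0.1) {
  if (anyDuplicated(best$qid)) stop("multiple hits per query; run bestHits()")
  miss <- setdiff(unique(best$sid), names(protein_lengths))
  if (length(miss)) stop("missing protein length for subject id: ", miss[1])
  plen <- unname(protein_lengths[best$sid])
  hit_bases <- abs(best$qend - best$qstart) + 1L
  ohr <- hit_bases / (3 * plen)
  records <- data.frame(qid = best$qid, sid = best$sid,
                        hit_bases = hit_bases, protein_len = plen,
                        ohr = ohr, stringsAsFactors = FALSE)
  classes <- c(full_length = sum(ohr >= 1), over_0.75 = sum(ohr > 0.75),
               over_0.5 = sum(ohr > 0.5), n = length(ohr))
  lows <- seq(0, 1 - bin_width, by = bin_width)
  counts <- as.integer(table(cut(ohr, breaks = c(lows, 1, Inf),
                                 right = FALSE)))
  bins <- data.frame(bin_low = c(lows, 1),
                     bin_high = c(lows + bin_width, NA_real_),
                     count = counts)
  list(records = records, classes = classes, bins = bins)
}

#' Minimal read-cleaning utility
#'
#' Drops reads containing any unknown base (N) and reads where more than
#' `max_low_frac` of bases fall below the quality threshold `min_q`.
#' Provided for completeness; raw read processing is upstream of the
#' Ks pipeline proper.
#'
#' @param seqs Character vector of read sequences.
#' @param quals Character vector of Phred+33 quality strings (same lengths).
#' @param min_q Minimum acceptable Phred score.
#' @param max_low_frac Maximum tolerated fraction of bases below `min_q`.
#' @return Logical vector: TRUE for reads to keep.
#' @export
cleanReads <- function(seqs, quals, min_q = 20L, max_low_frac = 0.10) {
  stopifnot(length(seqs) == length(quals),
            all(nchar(seqs) == nchar(quals)))
  has_n <- grepl("N", seqs, fixed = TRUE)
  low_frac <- vapply(quals, function(q) {
    ph <- utf8ToInt(q) - 33L
    mean(ph < min_q)
  }, numeric(1), USE.NAMES = FALSE)
  !has_n & low_frac <= max_low_frac
}
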