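#' Global protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gap costs
#' (open 10, extend 0.5 by default), as a prerequisite for codon alignment.
#'
#' @param prot_a,prot_b Protein sequences (character or AAString), no
#'   internal stops.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return List with `a`, `b` (aligned strings with `-` gaps) and `score`.
#' @export
alignProteins <- function(prot_a, prot_b, gap_opening = 10,
                          gap_extension = 0.5) {
  prot_a <- as.character(prot_a); prot_b <- as.character(prot_b)
  if (!nzchar(prot_a) || !nzchar(prot_b)) stop("empty protein sequence")
  if (grepl("*", paste0(prot_a, prot_b), fixed = TRUE))
    stop("proteins must not contain stop codons")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    substitutionMatrix = .blosum62(), gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

.blosum62 <- function() {
  if (is.null(.ksd_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .ksd_cache$blosum62 <- e$BLOSUM62
  }
  .ksd_cache$blosum62
}

#' Back-translate an aligned protein pair to a codon alignment
#'
#' Maps each aligned residue back to its source codon; gap residues become
#' `---`. Columns where either codon contains a gap or an N are retained in
#' the alignment but excluded from the ungapped set used for Ks estimation.
#'
#' @param aln Alignment from [alignProteins()].
#' @param cds_a,cds_b In-frame coding sequences (character or DNAString);
#'   their lengths must equal 3x the ungapped protein lengths.
#' @param id_a,id_b Sequence identifiers carried into downstream estimates.
#' @return Object of class `ksd_codon_aln`: list with `id_a`, `id_b`,
#'   `codons_a`, `codons_b` (aligned codon triplets), `n_cols`,
#'   `n_ungapped`, and `idx_a`, `idx_b` (codon-table indices of the
#'   ungapped, N-free columns).
#' @export
backTranslate <- function(aln, cds_a, cds_b, id_a = "a", id_b = "b") {
  cds_a <- toupper(as.character(cds_a)); cds_b <- toupper(as.character(cds_b))
  res_a <- strsplit(aln$a, "")[[1]]; res_b <- strsplit(aln$b, "")[[1]]
  if (length(res_a) != length(res_b)) stop("aligned rows differ in length")
  n_res_a <- sum(res_a != "-"); n_res_b <- sum(res_b != "-")
  if (3L * n_res_a != nchar(cds_a))
    stop(sprintf("cds_a length %d != 3 x %d aligned residues",
                 nchar(cds_a), n_res_a))
  if (3L * n_res_b != nchar(cds_b))
    stop(sprintf("cds_b length %d != 3 x %d aligned residues",
                 nchar(cds_b), n_res_b))
  fill <- function(res, cds) {
    codons <- .split_codons(cds)
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    out
  }
  codons_a <- fill(res_a, cds_a)
  codons_b <- fill(res_b, cds_b)
  tab <- codonTable()
  ia <- match(codons_a, tab$codons)  # NA for gaps and N-containing codons
  ib <- match(codons_b, tab$codons)
  ok <- !is.na(ia) & !is.na(ib)
  structure(list(id_a = id_a, id_b = id_b,
                 codons_a = codons_a, codons_b = codons_b,
                 n_cols = length(codons_a), n_ungapped = sum(ok),
                 idx_a = ia[ok], idx_b = ib[ok]),
            class = "ksd_codon_aln")
}

#' @export
print.ksd_codon_aln <- function(x, ...) {
  cat(sprintf("Codon alignment %s / %s: %d columns (%d ungapped)\n",
              x$id_a, x$id_b, x$n_cols, x$n_ungapped))
  invisible(x)
}

#' Align a CDS pair and estimate Ks/Ka
#'
#' Convenience wrapper: translate both coding sequences, align the proteins,
#' back-translate to a codon alignment and run the requested estimator.
#'
#' @param cds_a,cds_b In-frame coding sequences (character or DNAString).
#' @param method `"YN00"` (production estimator) or `"NG86"`.
#' @param id_a,id_b Identifiers for the output row.
#' @param ... Passed to [ksYN00()] / [ksNG86()].
#' @return One-row data.frame as documented in [ksNG86()].
#' @export
pairKs <- function(cds_a, cds_b, method = c("YN00", "NG86"),
                   id_a = "a", id_b = "b", ...) {
  method <- match.arg(method)
  cds_a <- toupper(as.character(cds_a)); cds_b <- toupper(as.character(cds_b))
  pa <- .translate_cds(cds_a); pb <- .translate_cds(cds_b)
  aln <- alignProteins(pa, pb)
  caln <- backTranslate(aln, cds_a, cds_b, id_a = id_a, id_b = id_b)
  if (method == "NG86") ksNG86(caln, ...) else ksYN00(caln, ...)
}

.translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X", no.init.codon = TRUE))
  if (endsWith(prot, "*")) stop("CDS carries a terminal stop; trim it first")
  if (grepl("*", prot, fixed = TRUE)) stop("CDS contains an internal stop")
  prot
}
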