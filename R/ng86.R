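## Jukes-Cantor correction of an observed proportion of differences.
## Returns NA (saturation) when p >= 3/4.
.jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

.ks_row <- function(id_a, id_b, method, S, N, Sd, Nd, kappa, ka, ks, flags) {
  data.frame(id_a = id_a, id_b = id_b, method = method,
             S = S, N = N, Sd = Sd, Nd = Nd, kappa = kappa,
             ka = ka, ks = ks,
             flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Nei-Gojobori (1986) Ks/Ka estimate
#'
#' Classical counting estimator on a codon alignment. Synonymous site counts
#' per codon are the per-position fractions of synonymous single-nucleotide
#' changes (changes to stop codons excluded from the denominator); the
#' pair's S is the mean of the two sequences' totals and N = 3L - S over the
#' L ungapped columns. Differences are counted by enumerating all shortest
#' substitution pathways between differing codons (pathways through stop
#' codons discarded, the rest equally weighted) and averaging the synonymous
#' and nonsynonymous step counts. Proportions pS = Sd/S and pN = Nd/N are
#' corrected for multiple hits with the Jukes-Cantor formula
#' d = -(3/4) ln(1 - (4/3) p); a proportion at or beyond the 3/4 domain
#' boundary yields an NA distance flagged `saturated`.
#'
#' @param aln A `ksd_codon_aln` from [backTranslate()].
#' @return One-row data.frame: id_a, id_b, method, S, N, Sd, Nd, kappa
#'   (fixed at 1 for NG86), ka, ks, flags (comma-separated; empty when
#'   clean).
#' @export
ksNG86 <- function(aln) {
  stopifnot(inherits(aln, "ksd_codon_aln"))
  if (aln$n_ungapped < 1L) stop("no ungapped codon columns to estimate from")
  tab <- codonTable()
  ia <- aln$idx_a; ib <- aln$idx_b
  L <- aln$n_ungapped
  S <- (sum(tab$s_sites[ia]) + sum(tab$s_sites[ib])) / 2
  N <- 3 * L - S

  Sd <- 0; Nd <- 0; fallback <- FALSE
  d <- which(ia != ib)
  if (length(d)) {
    key <- paste0(pmin(ia[d], ib[d]), "_", pmax(ia[d], ib[d]))
    tally <- table(key)
    for (k in seq_along(tally)) {
      ij <- as.integer(strsplit(names(tally)[k], "_", fixed = TRUE)[[1]])
      cnt <- ng86PairCounts(ij[1], ij[2], tab)
      mult <- as.numeric(tally[k])
      Sd <- Sd + mult * cnt[["sd"]]
      Nd <- Nd + mult * cnt[["nd"]]
      if (cnt[["fallback"]] > 0) fallback <- TRUE
    }
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ks <- .jc_correct(ps)
  ka <- .jc_correct(pn)
  flags <- character(0)
  if (is.na(ks)) flags <- c(flags, "saturated_ks")
  if (is.na(ka)) flags <- c(flags, "saturated_ka")
  if (fallback) flags <- c(flags, "fallback_pathways")
  .ks_row(aln$id_a, aln$id_b, "NG86", S, N, Sd, Nd, 1, ka, ks, flags)
}
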