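## Internal codon bookkeeping shared by the Ks estimators and the sequence
## simulator. Codons are indexed 1..64 with nucleotide order A,C,G,T at each
## position (index = 16*p1 + 4*p2 + p3 + 1).

.ksd_cache <- new.env(parent = emptyenv())

.NT <- c("A", "C", "G", "T")

## transition partner of each nucleotide (A<->G, C<->T)
.TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")

.nt_index <- function(nt) match(nt, .NT) - 1L

#' @noRd
codonTable <- function() {
  if (!is.null(.ksd_cache$codon_table)) return(.ksd_cache$codon_table)
  grid <- expand.grid(p3 = .NT, p2 = .NT, p1 = .NT,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  nt_mat <- cbind(grid$p1, grid$p2, grid$p3)
  is_stop <- aa == "*"

  ## neighbor index: nb[i, pos, k] = codon obtained from codon i by setting
  ## position pos to the k-th nucleotide (A,C,G,T); equals i when unchanged
  nb <- array(0L, dim = c(64L, 3L, 4L))
  for (pos in 1:3) {
    for (k in 1:4) {
      nts <- nt_mat
      nts[, pos] <- .NT[k]
      nb[, pos, k] <- 16L * .nt_index(nts[, 1]) + 4L * .nt_index(nts[, 2]) +
        .nt_index(nts[, 3]) + 1L
    }
  }

  ## NG86-style synonymous site fraction per codon and position: among the 3
  ## single-nucleotide changes at that position, the fraction that are
  ## synonymous, with changes creating stop codons dropped from the
  ## denominator.
  syn_frac <- matrix(NA_real_, 64L, 3L)
  for (i in seq_len(64L)) {
    if (is_stop[i]) next
    for (pos in 1:3) {
      alt <- nb[i, pos, ]
      alt <- alt[alt != i]
      alt <- alt[!is_stop[alt]]
      syn_frac[i, pos] <- if (length(alt) == 0L) 0 else
        mean(aa[alt] == aa[i])
    }
  }
  s_sites <- rowSums(syn_frac)  # synonymous sites per codon (NA for stops)

  ## degeneracy class per codon/position: 4 if every non-stop change is
  ## synonymous (fourfold), 0 if every non-stop change is nonsynonymous,
  ## 2 otherwise. Used by the kappa estimator.
  degeneracy <- matrix(NA_integer_, 64L, 3L)
  for (i in seq_len(64L)) {
    if (is_stop[i]) next
    for (pos in 1:3) {
      alt <- nb[i, pos, ]
      alt <- alt[alt != i]
      alt <- alt[!is_stop[alt]]
      syn <- aa[alt] == aa[i]
      degeneracy[i, pos] <- if (length(alt) && all(syn)) 4L
        else if (!length(alt) || all(!syn)) 0L else 2L
    }
  }

  tab <- list(codons = codons, aa = aa, is_stop = is_stop, nt = nt_mat,
              nb = nb, syn_frac = syn_frac, s_sites = s_sites,
              degeneracy = degeneracy,
              sense = which(!is_stop))
  .ksd_cache$codon_table <- tab
  tab
}

## is a single-nucleotide change nt1 -> nt2 a transition?
.is_ts <- function(nt1, nt2) .TS_PARTNER[nt1] == nt2

#' Enumerate all shortest substitution pathways between two codons
#'
#' Pathways visiting a stop codon are discarded. Each pathway is a matrix
#' with one row per step and columns `syn` (1 = synonymous), `ts`
#' (1 = transition) and `to` (index of the codon the step lands on).
#' @noRd
codonPathways <- function(i, j, tab = codonTable()) {
  stopifnot(!tab$is_stop[i], !tab$is_stop[j])
  diff_pos <- which(tab$nt[i, ] != tab$nt[j, ])
  nd <- length(diff_pos)
  if (nd == 0L) return(list())
  perms <- if (nd == 1L) list(diff_pos)
    else if (nd == 2L) list(diff_pos, rev(diff_pos))
    else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(o) diff_pos[o])
    }
  out <- list()
  for (ord in perms) {
    cur <- i
    steps <- matrix(0, nrow = nd, ncol = 3,
                    dimnames = list(NULL, c("syn", "ts", "to")))
    ok <- TRUE
    for (s in seq_len(nd)) {
      pos <- ord[s]
      new_nt <- tab$nt[j, pos]
      nxt <- tab$nb[cur, pos, .nt_index(new_nt) + 1L]
      if (tab$is_stop[nxt]) { ok <- FALSE; break }
      steps[s, "syn"] <- as.numeric(tab$aa[nxt] == tab$aa[cur])
      steps[s, "ts"] <- as.numeric(.is_ts(tab$nt[cur, pos], new_nt))
      steps[s, "to"] <- nxt
      cur <- nxt
    }
    if (ok) out[[length(out) + 1L]] <- steps
  }
  out
}

#' Equal-weight (NG86) pathway summary for a codon pair, cached
#'
#' Returns c(sd, nd, sd_ts, sd_tv, nd_ts, nd_tv, fallback). When every
#' shortest pathway passes through a stop codon, the raw nucleotide
#' differences are split in proportion to the pair's synonymous/nonsynonymous
#' site fractions (fallback = 1).
#' @noRd
ng86PairCounts <- function(i, j, tab = codonTable()) {
  if (i > j) { k <- i; i <- j; j <- k }
  key <- paste0(i, "_", j)
  cache <- .ksd_cache$ng86_pairs
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .ksd_cache$ng86_pairs <- cache
  }
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  paths <- codonPathways(i, j, tab)
  diff_pos <- which(tab$nt[i, ] != tab$nt[j, ])
  if (length(paths) == 0L && length(diff_pos) > 0L) {
    ## all pathways blocked by stops: split raw differences by site type
    s_i <- tab$s_sites[i]; s_j <- tab$s_sites[j]
    fs <- (s_i + s_j) / 6  # mean synonymous fraction of the two codons
    nd_tot <- length(diff_pos)
    ts <- vapply(diff_pos, function(p) .is_ts(tab$nt[i, p], tab$nt[j, p]),
                 logical(1))
    res <- c(sd = nd_tot * fs, nd = nd_tot * (1 - fs),
             sd_ts = sum(ts) * fs, sd_tv = sum(!ts) * fs,
             nd_ts = sum(ts) * (1 - fs), nd_tv = sum(!ts) * (1 - fs),
             fallback = 1)
  } else if (length(diff_pos) == 0L) {
    res <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0,
             fallback = 0)
  } else {
    m <- Reduce(`+`, lapply(paths, function(st) {
      c(sd = sum(st[, "syn"]), nd = sum(1 - st[, "syn"]),
        sd_ts = sum(st[, "syn"] * st[, "ts"]),
        sd_tv = sum(st[, "syn"] * (1 - st[, "ts"])),
        nd_ts = sum((1 - st[, "syn"]) * st[, "ts"]),
        nd_tv = sum((1 - st[, "syn"]) * (1 - st[, "ts"])))
    })) / length(paths)
    res <- c(m, fallback = 0)
  }
  cache[[key]] <- res
  res
}

## codon string vector -> integer indices (NA for codons containing non-ACGT)
.codons_to_index <- function(codon_chr) {
  tab <- codonTable()
  idx <- match(codon_chr, tab$codons)
  idx
}

## split a nucleotide string into codon strings
.split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
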