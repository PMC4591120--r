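#' Yang-Nielsen (2000) approximate Ks/Ka estimate
#'
#' Approximate-method estimator accounting for transition/transversion rate
#' bias and codon usage. Codon frequencies follow the F3x4 model (position-
#' specific nucleotide frequencies pooled over both sequences). The
#' transition/transversion ratio kappa is estimated from site classes where
#' selection cannot distort the ratio: positions that are fourfold
#' degenerate in both codons (all changes synonymous) and positions that
#' are nondegenerate in both (all changes nonsynonymous), each corrected
#' with the Kimura two-parameter formulas and combined weighted by site
#' counts; the estimate is iterated from kappa = 2 until it changes by less
#' than `tol`. Site counts S and N weight each possible change by
#' kappa^(transition) times the frequency of the target codon; differences
#' are partitioned over shortest substitution pathways weighted the same
#' way (pathways through stops discarded). Synonymous and nonsynonymous
#' distances are corrected separately with the Kimura two-parameter
#' correction on their transition/transversion splits; out-of-domain
#' corrections are flagged `saturated`, never clamped.
#'
#' @param aln A `ksd_codon_aln` from [backTranslate()] with at least 10
#'   ungapped columns.
#' @param fix_kappa Optional fixed kappa (skips estimation); e.g. 1 for the
#'   no-bias limiting case in which S and N reduce to the NG86 counts under
#'   uniform codon frequencies.
#' @param freqs `"f3x4"` (default) or `"uniform"` codon frequencies.
#' @param tol Convergence tolerance on kappa.
#' @param max_iter Maximum kappa iterations; non-convergence is flagged and
#'   the last iterate is used.
#' @return One-row data.frame as in [ksNG86()] (method `"YN00"`, estimated
#'   kappa).
#' @export
ksYN00 <- function(aln, fix_kappa = NULL, freqs = c("f3x4", "uniform"),
                   tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(aln, "ksd_codon_aln"))
  freqs <- match.arg(freqs)
  if (aln$n_ungapped < 10L)
    stop("YN00 requires >= 10 ungapped codon columns (got ",
         aln$n_ungapped, ")")
  tab <- codonTable()
  ia <- aln$idx_a; ib <- aln$idx_b
  L <- aln$n_ungapped
  flags <- character(0)

  pi_codon <- .yn00_codon_freqs(c(ia, ib), freqs, tab)

  ## --- kappa ---------------------------------------------------------
  if (!is.null(fix_kappa)) {
    kappa <- fix_kappa
  } else {
    est <- .yn00_kappa(ia, ib, tab)
    if (is.na(est)) {
      kappa <- 2
      flags <- c(flags, "kappa_fallback")
    } else {
      ## the site-class estimate does not depend on the current kappa, so
      ## the iteration from kappa = 2 settles on the second pass; the loop
      ## guards the general case
      kappa <- 2
      for (it in seq_len(max_iter)) {
        knew <- est
        if (abs(knew - kappa) < tol) break
        kappa <- knew
      }
      if (abs(est - kappa) >= tol) flags <- c(flags, "kappa_nonconverged")
      kappa <- est
    }
  }

  ## --- sites ----------------------------------------------------------
  s_codon <- .yn00_site_counts(kappa, pi_codon, tab)
  S <- (sum(s_codon[ia]) + sum(s_codon[ib])) / 2
  N <- 3 * L - S

  ## --- differences ----------------------------------------------------
  acc <- c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  fallback <- FALSE
  d <- which(ia != ib)
  if (length(d)) {
    key <- paste0(ia[d], "_", ib[d])
    tally <- table(key)
    for (k in seq_along(tally)) {
      ij <- as.integer(strsplit(names(tally)[k], "_", fixed = TRUE)[[1]])
      cnt <- .yn00_pair_diffs(ij[1], ij[2], kappa, pi_codon, tab)
      acc <- acc + as.numeric(tally[k]) * cnt[1:4]
      if (cnt[["fallback"]] > 0) fallback <- TRUE
    }
  }
  Sd <- acc[["sd_ts"]] + acc[["sd_tv"]]
  Nd <- acc[["nd_ts"]] + acc[["nd_tv"]]

  ## --- K2P correction per site class ---------------------------------
  ks <- .k2p_distance(acc[["sd_ts"]] / S, acc[["sd_tv"]] / S)
  ka <- .k2p_distance(acc[["nd_ts"]] / N, acc[["nd_tv"]] / N)
  if (is.na(ks)) flags <- c(flags, "saturated_ks")
  if (is.na(ka)) flags <- c(flags, "saturated_ka")
  if (fallback) flags <- c(flags, "fallback_pathways")
  .ks_row(aln$id_a, aln$id_b, "YN00", S, N, Sd, Nd, kappa, ka, ks, flags)
}

## Kimura two-parameter distance from transition (P) and transversion (Q)
## proportions; NA when outside the correction domain.
.k2p_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (is.na(w1) || is.na(w2) || w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

## F3x4 (or uniform) codon frequencies over the 61 sense codons.
.yn00_codon_freqs <- function(codon_idx, freqs, tab) {
  pi_codon <- numeric(64L)
  if (freqs == "uniform") {
    pi_codon[tab$sense] <- 1 / length(tab$sense)
    return(pi_codon)
  }
  nt_f <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, .NT))
  for (pos in 1:3) {
    cnt <- table(factor(tab$nt[codon_idx, pos], levels = .NT))
    nt_f[pos, ] <- as.numeric(cnt) / sum(cnt)
  }
  p <- nt_f[1, tab$nt[, 1]] * nt_f[2, tab$nt[, 2]] * nt_f[3, tab$nt[, 3]]
  p[tab$is_stop] <- 0
  tot <- sum(p)
  if (tot <= 0) {  # degenerate composition; fall back to uniform
    pi_codon[tab$sense] <- 1 / length(tab$sense)
    return(pi_codon)
  }
  p / tot
}

## kappa from fourfold-degenerate and nondegenerate site classes (K2P on
## each class, combined weighted by site counts); NA when inestimable.
.yn00_kappa <- function(ia, ib, tab) {
  L4 <- 0; ts4 <- 0; tv4 <- 0
  L0 <- 0; ts0 <- 0; tv0 <- 0
  for (pos in 1:3) {
    da <- tab$degeneracy[ia, pos]
    db <- tab$degeneracy[ib, pos]
    na_ <- tab$nt[ia, pos]; nb_ <- tab$nt[ib, pos]
    differs <- na_ != nb_
    is_ts <- differs & (.TS_PARTNER[na_] == nb_)
    four <- da == 4L & db == 4L
    zero <- da == 0L & db == 0L
    L4 <- L4 + sum(four); ts4 <- ts4 + sum(four & is_ts)
    tv4 <- tv4 + sum(four & differs & !is_ts)
    L0 <- L0 + sum(zero); ts0 <- ts0 + sum(zero & is_ts)
    tv0 <- tv0 + sum(zero & differs & !is_ts)
  }
  k2p_AB <- function(P, Q) {
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) return(c(NA_real_, NA_real_))
    c(A = -0.5 * log(w1) + 0.25 * log(w2), B = -0.5 * log(w2))
  }
  cls <- list()
  if (L4 >= 1) cls$f4 <- c(L4, k2p_AB(ts4 / L4, tv4 / L4))
  if (L0 >= 1) cls$f0 <- c(L0, k2p_AB(ts0 / L0, tv0 / L0))
  cls <- Filter(function(x) !anyNA(x), cls)
  if (!length(cls)) return(NA_real_)
  w <- vapply(cls, `[`, numeric(1), 1)
  A <- sum(w * vapply(cls, `[`, numeric(1), 2)) / sum(w)
  B <- sum(w * vapply(cls, `[`, numeric(1), 3)) / sum(w)
  if (!is.finite(A) || !is.finite(B) || B <= 1e-9 || A <= 0) return(NA_real_)
  2 * A / B
}

## per-codon synonymous site counts under kappa and codon frequencies;
## per position, each change is weighted by pi(target codon) *
## kappa^(transition), stops excluded; the synonymous fraction of total
## weight gives the site share, so s + n = 3 per codon.
.yn00_site_counts <- function(kappa, pi_codon, tab) {
  s <- rep(NA_real_, 64L)
  for (i in tab$sense) {
    si <- 0
    for (pos in 1:3) {
      alt <- tab$nb[i, pos, ]
      alt <- alt[alt != i]
      keep <- !tab$is_stop[alt]
      alt <- alt[keep]
      if (!length(alt)) next
      ts <- .is_ts(tab$nt[i, pos], tab$nt[alt, pos])
      w <- pi_codon[alt] * ifelse(ts, kappa, 1)
      tw <- sum(w)
      if (tw <= 0) {
        si <- si + tab$syn_frac[i, pos]  # degenerate weights: plain fraction
      } else {
        si <- si + sum(w[tab$aa[alt] == tab$aa[i]]) / tw
      }
    }
    s[i] <- si
  }
  s
}

## kappa/frequency-weighted pathway decomposition of one codon pair.
.yn00_pair_diffs <- function(i, j, kappa, pi_codon, tab) {
  paths <- codonPathways(i, j, tab)
  if (!length(paths)) {
    ## all pathways stop-blocked: reuse the proportional fallback
    cnt <- ng86PairCounts(i, j, tab)
    return(c(sd_ts = cnt[["sd_ts"]], sd_tv = cnt[["sd_tv"]],
             nd_ts = cnt[["nd_ts"]], nd_tv = cnt[["nd_tv"]], fallback = 1))
  }
  wts <- vapply(paths, function(st) {
    prod(pi_codon[st[, "to"]] * ifelse(st[, "ts"] == 1, kappa, 1))
  }, numeric(1))
  if (sum(wts) <= 0) wts <- rep(1, length(paths))  # degenerate frequencies
  wts <- wts / sum(wts)
  acc <- c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  for (k in seq_along(paths)) {
    st <- paths[[k]]
    acc <- acc + wts[k] * c(
      sd_ts = sum(st[, "syn"] * st[, "ts"]),
      sd_tv = sum(st[, "syn"] * (1 - st[, "ts"])),
      nd_ts = sum((1 - st[, "syn"]) * st[, "ts"]),
      nd_tv = sum((1 - st[, "syn"]) * (1 - st[, "ts"])))
  }
  c(acc, fallback = 0)
}
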