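# Independent reference implementations used to cross-check the package.
# Deliberately written as plain string/loop code with no shared machinery.

oracle_gc <- Biostrings::GENETIC_CODE

# NG86 synonymous sites of one codon (per-position fractions, stop targets
# excluded from the denominator)
oracle_syn_sites <- function(codon) {
  aa <- oracle_gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      maa <- oracle_gc[[mut]]
      if (maa == "*") next
      valid <- valid + 1
      if (maa == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Equal-weight shortest-pathway decomposition of the differences between two
# sense codons; NA when every pathway passes through a stop codon.
oracle_pair_diffs <- function(c1, c2) {
  x1 <- strsplit(c1, "")[[1]]; x2 <- strsplit(c2, "")[[1]]
  pos <- which(x1 != x2)
  if (!length(pos)) return(c(sd = 0, nd = 0, n_paths = 0))
  acc <- NULL; n_ok <- 0
  for (ord in oracle_perms(pos)) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_gc[[nxt]] == "*") { ok <- FALSE; break }
      if (oracle_gc[[nxt]] == oracle_gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) {
      acc <- if (is.null(acc)) c(sd, nd) else acc + c(sd, nd)
      n_ok <- n_ok + 1
    }
  }
  if (n_ok == 0) return(c(sd = NA_real_, nd = NA_real_, n_paths = 0))
  c(sd = acc[1] / n_ok, nd = acc[2] / n_ok, n_paths = n_ok)
}

# Brute-force N50: walk the descending lengths with an explicit loop.
oracle_n50 <- function(lengths) {
  srt <- sort(lengths, decreasing = TRUE)
  half <- sum(as.numeric(lengths)) / 2
  run <- 0
  for (l in srt) {
    run <- run + l
    if (run >= half) return(l)
  }
  NA_integer_
}

sense_codons <- names(oracle_gc)[oracle_gc != "*"]

random_sense_codon_pair <- function() {
  sample(sense_codons, 2, replace = TRUE)
}
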