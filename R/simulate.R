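#' Random stop-free coding sequence
#'
#' Codons drawn uniformly from the 61 sense codons; the first codon is ATG.
#'
#' @param n_codons Length in codons (>= 1).
#' @param seed Integer seed.
#' @return Character string of length 3 * n_codons.
#' @export
randomCds <- function(n_codons, seed = 1L) {
  stopifnot(n_codons >= 1L)
  tab <- codonTable()
  set.seed(seed)
  idx <- sample(tab$sense, n_codons, replace = TRUE)
  idx[1] <- match("ATG", tab$codons)
  paste(tab$codons[idx], collapse = "")
}

## --- proposal-acceptance substitution process -----------------------------

## probability that a single proposal event on `codon_idx` is an accepted
## synonymous change, given kappa (per-position tables, then averaged over
## the sequence). Proposals: site uniform, target nucleotide with
## transition:transversion weight kappa:1; stop-creating changes rejected,
## nonsynonymous changes accepted with probability omega (not part of the
## synonymous acceptance probability).
.p_syn_proposal <- function(codon_idx, kappa, tab = codonTable()) {
  key <- paste0("psyn_", kappa)
  tabp <- .ksd_cache[[key]]
  if (is.null(tabp)) {
    tabp <- matrix(NA_real_, 64L, 3L)
    for (i in tab$sense) {
      for (pos in 1:3) {
        alt <- tab$nb[i, pos, ]
        alt <- alt[alt != i]
        ts <- .is_ts(tab$nt[i, pos], tab$nt[alt, pos])
        w <- ifelse(ts, kappa, 1)
        w <- w / sum(w)
        ok <- !tab$is_stop[alt] & tab$aa[alt] == tab$aa[i]
        tabp[i, pos] <- sum(w[ok])
      }
    }
    .ksd_cache[[key]] <- tabp
  }
  mean(tabp[codon_idx, ])
}

## evolve one lineage for `branch_ks` expected synonymous substitutions per
## synonymous site; returns list(idx, syn, nonsyn). `n_prop_mult` rescales
## the proposal count (calibration hook).
.branch_evolve <- function(codon_idx, branch_ks, omega, kappa,
                           n_prop_mult = 1) {
  if (branch_ks <= 0) return(list(idx = codon_idx, syn = 0L, nonsyn = 0L))
  tab <- codonTable()
  L <- length(codon_idx)
  S <- sum(tab$s_sites[codon_idx])
  p_syn <- .p_syn_proposal(codon_idx, kappa, tab)
  n_prop <- max(0L, as.integer(round(n_prop_mult * branch_ks * S / p_syn)))
  syn <- 0L; nonsyn <- 0L
  if (n_prop == 0L) return(list(idx = codon_idx, syn = syn, nonsyn = nonsyn))
  sites <- sample.int(3L * L, n_prop, replace = TRUE)
  u_nt <- stats::runif(n_prop)
  u_acc <- stats::runif(n_prop)
  for (e in seq_len(n_prop)) {
    s <- sites[e]
    cpos <- ((s - 1L) %/% 3L) + 1L
    npos <- ((s - 1L) %% 3L) + 1L
    cur <- codon_idx[cpos]
    cur_nt <- tab$nt[cur, npos]
    alts <- setdiff(.NT, cur_nt)
    w <- ifelse(alts == .TS_PARTNER[cur_nt], kappa, 1)
    w <- cumsum(w / sum(w))
    new_nt <- alts[findInterval(u_nt[e], w) + 1L]
    nxt <- tab$nb[cur, npos, .nt_index(new_nt) + 1L]
    if (tab$is_stop[nxt]) next
    if (tab$aa[nxt] == tab$aa[cur]) {
      codon_idx[cpos] <- nxt
      syn <- syn + 1L
    } else if (u_acc[e] < omega) {
      codon_idx[cpos] <- nxt
      nonsyn <- nonsyn + 1L
    }
  }
  list(idx = codon_idx, syn = syn, nonsyn = nonsyn)
}

## Pilot-based calibration: multiplier on the proposal count such that the
## expected Ks estimate of an evolved pair, under the chosen estimator,
## equals target_ks. NG86 and YN00 count synonymous sites differently under
## transition bias (NG86 ignores kappa and undercounts S), so the two
## estimators disagree systematically by a few percent at kappa > 1 and each
## needs its own constant. Two pilot rounds of `n_pilot/2` replicates each;
## cached per configuration (the pilot runs on its own deterministic seed
## stream so the constant is reproducible).
.evolve_calibration <- function(n_codons, target_ks, omega, kappa,
                                estimator = "NG86", n_pilot = 1000L) {
  key <- sprintf("cal_%s_%d_%g_%g_%g", estimator, n_codons, target_ks,
                 omega, kappa)
  hit <- .ksd_cache[[key]]
  if (!is.null(hit)) return(hit)
  pilot_seed <- 19937L
  half <- max(20L, n_pilot %/% 2L)
  est_fun <- if (estimator == "YN00")
    function(ia, ib) ksYN00(.caln_from_idx(ia, ib))$ks
  else .ng86_from_idx
  mean_ks <- function(mult, seed0, reps) {
    est <- numeric(reps)
    for (r in seq_len(reps)) {
      anc <- .codons_to_index(.split_codons(
        randomCds(n_codons, seed = seed0 + r)))
      set.seed(seed0 + 500000L + r)
      a <- .branch_evolve(anc, target_ks / 2, omega, kappa, mult)
      b <- .branch_evolve(anc, target_ks / 2, omega, kappa, mult)
      est[r] <- est_fun(a$idx, b$idx)
    }
    mean(est, na.rm = TRUE)
  }
  m1 <- mean_ks(1, pilot_seed, half)
  c1 <- if (is.finite(m1) && m1 > 0) target_ks / m1 else 1
  m2 <- mean_ks(c1, pilot_seed + 1000000L, half)
  c2 <- if (is.finite(m2) && m2 > 0) c1 * target_ks / m2 else c1
  .ksd_cache[[key]] <- c2
  c2
}

## NG86 ks straight from two equal-length codon-index vectors (no alignment;
## used by the calibration pilot).
.ng86_from_idx <- function(ia, ib) {
  tab <- codonTable()
  L <- length(ia)
  S <- (sum(tab$s_sites[ia]) + sum(tab$s_sites[ib])) / 2
  Sd <- 0
  d <- which(ia != ib)
  for (k in d) {
    cnt <- ng86PairCounts(min(ia[k], ib[k]), max(ia[k], ib[k]), tab)
    Sd <- Sd + cnt[["sd"]]
  }
  .jc_correct(Sd / S)
}

## codon alignment object straight from two equal-length codon-index
## vectors (substitution-only simulations need no protein alignment)
.caln_from_idx <- function(ia, ib, id_a = "a", id_b = "b") {
  tab <- codonTable()
  structure(list(id_a = id_a, id_b = id_b,
                 codons_a = tab$codons[ia], codons_b = tab$codons[ib],
                 n_cols = length(ia), n_ungapped = length(ia),
                 idx_a = ia, idx_b = ib),
            class = "ksd_codon_aln")
}

#' Evolve a duplicated pair of coding sequences
#'
#' Two descendants of `ancestor` evolve independently for half the target
#' Ks each under a mechanistic proposal-acceptance process: substitutions
#' are proposed per nucleotide site with transition:transversion weight
#' kappa:1; a change creating a stop codon is rejected; a nonsynonymous
#' change is accepted with probability `omega`, a synonymous one always.
#' Multiple hits and back-substitutions occur naturally, so the multiple-hit
#' corrections in the estimators are genuinely exercised. The proposal
#' count is calibrated (pilot simulation, cached per configuration) so the
#' expected estimated Ks of the pair equals `target_ks` under the estimator
#' named by `calibrate_to` (NG86 by default); the target is therefore an
#' expectation, not an exact realization. Because NG86 undercounts
#' synonymous sites when transition bias is present while YN00 accounts for
#' it, the two estimators differ systematically by a few percent at
#' kappa > 1; recovery studies should calibrate to the estimator they
#' evaluate.
#'
#' @param ancestor Stop-free in-frame CDS (character).
#' @param target_ks Expected pair Ks (>= 0).
#' @param omega Ka/Ks acceptance probability for nonsynonymous changes.
#' @param kappa Transition/transversion rate ratio of the proposal process.
#' @param seed Integer seed.
#' @param calibrate Use the pilot calibration (TRUE) or the analytic
#'   first-order proposal count only (FALSE; cheaper, adequate for
#'   qualitative fixtures).
#' @param calibrate_to Estimator whose expectation the calibration targets.
#' @return List: `a`, `b` (descendant CDS strings), `realized`
#'   (data.frame: branch, syn, nonsyn substitution counts).
#' @export
evolvePair <- function(ancestor, target_ks, omega = 0.2, kappa = 2,
                       seed = 1L, calibrate = TRUE,
                       calibrate_to = c("NG86", "YN00")) {
  calibrate_to <- match.arg(calibrate_to)
  if (omega < 0) stop("omega must be >= 0")
  if (target_ks < 0) stop("target_ks must be >= 0")
  anc <- .codons_to_index(.split_codons(toupper(ancestor)))
  if (anyNA(anc)) stop("ancestor must be an in-frame ACGT sequence")
  tab <- codonTable()
  if (any(tab$is_stop[anc])) stop("ancestor contains a stop codon")
  mult <- if (calibrate && target_ks > 0)
    .evolve_calibration(length(anc), target_ks, omega, kappa,
                        estimator = calibrate_to) else 1
  set.seed(seed)
  a <- .branch_evolve(anc, target_ks / 2, omega, kappa, mult)
  b <- .branch_evolve(anc, target_ks / 2, omega, kappa, mult)
  list(a = paste(tab$codons[a$idx], collapse = ""),
       b = paste(tab$codons[b$idx], collapse = ""),
       realized = data.frame(branch = c("a", "b"),
                             syn = c(a$syn, b$syn),
                             nonsyn = c(a$nonsyn, b$nonsyn)))
}

#' Evolve a gene family with known duplication depths
#'
#' Sequential duplications at the given node-Ks depths produce
#' `length(duplication_ks) + 1` leaves whose true single-linkage node
#' heights equal `duplication_ks` (each lineage accumulates half a node's
#' Ks since its split). Uses the analytic (uncalibrated) proposal count per
#' branch segment.
#'
#' @param ancestor Stop-free in-frame CDS (character).
#' @param duplication_ks Node Ks depth of each duplication (>= 1 value).
#' @param omega,kappa As in [evolvePair()].
#' @param seed Integer seed.
#' @param prefix Leaf id prefix.
#' @return List: `leaves` (named character vector of CDS),
#'   `true_node_ks` (sorted duplication depths).
#' @export
evolveFamily <- function(ancestor, duplication_ks, omega = 0.2, kappa = 2,
                         seed = 1L, prefix = "g") {
  stopifnot(length(duplication_ks) >= 1L, all(duplication_ks >= 0))
  tab <- codonTable()
  anc <- .codons_to_index(.split_codons(toupper(ancestor)))
  if (anyNA(anc) || any(tab$is_stop[anc]))
    stop("ancestor must be a stop-free in-frame ACGT sequence")
  set.seed(seed)
  ages <- sort(duplication_ks, decreasing = TRUE) / 2
  leaves <- list()
  cur <- anc
  cur_age <- ages[1]
  for (k in seq_along(ages)) {
    ## duplication at ages[k]: evolve the main lineage down to this age
    if (k > 1L) {
      seg <- .branch_evolve(cur, cur_age - ages[k], omega, kappa)
      cur <- seg$idx
      cur_age <- ages[k]
    }
    side <- .branch_evolve(cur, ages[k], omega, kappa)
    leaves[[length(leaves) + 1L]] <- side$idx
  }
  main <- .branch_evolve(cur, cur_age, omega, kappa)
  leaves[[length(leaves) + 1L]] <- main$idx
  out <- vapply(leaves, function(i) paste(tab$codons[i], collapse = ""),
                character(1))
  names(out) <- paste0(prefix, seq_along(out))
  list(leaves = out, true_node_ks = sort(duplication_ks))
}

#' Sample Ks values from a lognormal mixture
#'
#' Component chosen by weight; ln Ks drawn normal(mu_k, sigma_k); draws
#' outside the open interval `range` are resampled (truncation by
#' resampling keeps component shapes intact inside the window).
#'
#' @param weights Mixing weights (sum to 1).
#' @param mu,sigma Ln-scale component means and standard deviations.
#' @param n Number of values.
#' @param seed Integer seed.
#' @param range Open truncation interval on the Ks scale.
#' @return Numeric vector of n Ks values in `range`.
#' @export
sampleKsMixture <- function(weights, mu, sigma, n = 529L, seed = 1L,
                            range = c(0, 2)) {
  stopifnot(length(weights) == length(mu), length(mu) == length(sigma),
            abs(sum(weights) - 1) < 1e-8, all(sigma >= 0))
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    m <- n - length(out)
    comp <- sample.int(length(weights), m, replace = TRUE, prob = weights)
    v <- exp(stats::rnorm(m, mu[comp], sigma[comp]))
    v <- v[v > range[1] & v < range[2]]
    out <- c(out, v)
  }
  out[seq_len(n)]
}

#' Toy all-by-all hit table with known surviving pairs
#'
#' Plants self-hits, reciprocal duplicates and threshold-straddling rows,
#' and returns the ground-truth surviving pair set computed by an
#' independent re-evaluation of the filter rules inside the generator.
#'
#' @param path Optional path; when given the table is written there in the
#'   12-column layout.
#' @param seed Seed for the randomised filler rows.
#' @param n_random Number of additional random passing pairs.
#' @return List: `hits` (data.frame), `expected_pairs` (data.frame id_a,
#'   id_b of pairs that survive the default filters), `path` (or NULL).
#' @export
toyHitTable <- function(path = NULL, seed = 1L, n_random = 10L) {
  row <- function(q, s, pid, len, ev, bits = 200) {
    data.frame(qid = q, sid = s, pident = pid, aln_len = as.integer(len),
               mismatches = as.integer(round(len * (100 - pid) / 100)),
               gapopens = 0L, qstart = 1L, qend = as.integer(len),
               sstart = 1L, send = as.integer(len), evalue = ev,
               bitscore = bits, stringsAsFactors = FALSE)
  }
  hits <- rbind(
    row("u1", "u1", 100, 500, 0),          # self-hit: excluded
    row("u1", "u2", 85.0, 400, 1e-80),     # passes
    row("u2", "u1", 85.0, 400, 1e-75),     # reciprocal duplicate: merged
    row("u2", "u3", 90.0, 149, 1e-40),     # fails aln_len
    row("u3", "u4", 39.9, 300, 1e-30),     # fails pident
    row("u4", "u5", 55.0, 300, 1e-4),      # fails evalue
    row("u5", "u6", 40.0, 150, 1e-5),      # boundary: passes (inclusive)
    row("u7", "u8", 70.0, 250, 1e-20))     # passes
  set.seed(seed)
  for (k in seq_len(n_random)) {
    a <- sprintf("r%02da", k); b <- sprintf("r%02db", k)
    hits <- rbind(hits, row(a, b, stats::runif(1, 45, 99),
                            sample(150:900, 1),
                            10^stats::runif(1, -120, -6)))
  }
  ## independent rule evaluation (kept deliberately plain)
  ok <- hits$qid != hits$sid & hits$evalue <= 1e-5 &
    hits$pident >= 40 & hits$aln_len >= 150
  pa <- pmin(hits$qid[ok], hits$sid[ok])
  pb <- pmax(hits$qid[ok], hits$sid[ok])
  expected <- unique(data.frame(id_a = pa, id_b = pb,
                                stringsAsFactors = FALSE))
  expected <- expected[order(expected$id_a, expected$id_b), , drop = FALSE]
  rownames(expected) <- NULL
  if (!is.null(path)) writeHits(hits, path)
  list(hits = hits, expected_pairs = expected, path = path)
}

#' Simulate a synthetic transcriptome with planted WGD events
#'
#' Builds every input the pipeline consumes - unigene FASTA, best-protein
#' hits, an all-by-all nucleotide hit table and a subject-protein FASTA -
#' from gene families evolved with [evolveFamily()] around the given event
#' Ks values, with lognormal scatter between families. Unigenes are the
#' coding sequences flanked by random UTRs so CDS extraction is exercised.
#'
#' @param n_young,n_old Number of two-member families at the young and old
#'   event.
#' @param n_both Number of three-member families carrying one node at each
#'   event.
#' @param event_ks Length-2 vector: young and old event Ks.
#' @param ln_sd Ln-scale scatter of family node depths around each event.
#' @param n_codons CDS length per gene, in codons.
#' @param omega,kappa Evolution parameters.
#' @param utr Range of random UTR lengths (bases) added at each end.
#' @param dir Output directory (created).
#' @param seed Integer seed.
#' @return List of paths: `unigenes`, `protein_hits`, `allbyall`,
#'   `proteins`, `ground_truth`; plus `truth` (the ground-truth list).
#' @export
simulateTranscriptome <- function(n_young = 300L, n_old = 180L,
                                  n_both = 25L,
                                  event_ks = c(0.25, 1.33),
                                  ln_sd = 0.08, n_codons = 300L,
                                  omega = 0.2, kappa = 2,
                                  utr = c(20L, 120L), dir = tempfile("simtx"),
                                  seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  specs <- c(
    lapply(seq_len(n_young), function(i) list(ev = 1L, sizes = 1L)),
    lapply(seq_len(n_old), function(i) list(ev = 2L, sizes = 1L)),
    lapply(seq_len(n_both), function(i) list(ev = c(1L, 2L), sizes = 2L)))
  depth_seed <- sample.int(2^30, length(specs))
  unigene <- character(0); truth_nodes <- list()
  allbyall <- list(); prot_hits <- list(); prot_seqs <- character(0)
  tab <- codonTable()
  for (f in seq_along(specs)) {
    sp <- specs[[f]]
    set.seed(depth_seed[f])
    times <- exp(stats::rnorm(length(sp$ev), log(event_ks[sp$ev]), ln_sd))
    anc <- randomCds(n_codons, seed = depth_seed[f] + 1L)
    fam <- evolveFamily(anc, times, omega = omega, kappa = kappa,
                        seed = depth_seed[f] + 2L,
                        prefix = sprintf("fam%04d_g", f))
    cds <- fam$leaves
    truth_nodes[[f]] <- data.frame(family = f,
                                   event = sp$ev[order(times)],
                                   node_ks = fam$true_node_ks)
    ## unigenes: UTR + CDS + UTR
    for (id in names(cds)) {
      u5 <- sample(utr[1]:utr[2], 1); u3 <- sample(utr[1]:utr[2], 1)
      full <- paste0(
        paste(sample(.NT, u5, replace = TRUE), collapse = ""),
        cds[[id]],
        paste(sample(.NT, u3, replace = TRUE), collapse = ""))
      unigene[id] <- full
      pid <- paste0("p_", id)
      prot <- .translate_cds(cds[[id]])
      prot_seqs[pid] <- prot
      prot_hits[[length(prot_hits) + 1L]] <- data.frame(
        qid = id, sid = pid, pident = 100, aln_len = nchar(prot),
        mismatches = 0L, gapopens = 0L,
        qstart = u5 + 1L, qend = u5 + nchar(cds[[id]]),
        sstart = 1L, send = nchar(prot), evalue = 0,
        bitscore = 2 * nchar(prot), stringsAsFactors = FALSE)
    }
    ## all-by-all rows for every member pair (plus a self-hit each)
    ids <- names(cds)
    for (id in ids) {
      allbyall[[length(allbyall) + 1L]] <- data.frame(
        qid = id, sid = id, pident = 100, aln_len = nchar(cds[[id]]),
        mismatches = 0L, gapopens = 0L, qstart = 1L,
        qend = nchar(cds[[id]]), sstart = 1L, send = nchar(cds[[id]]),
        evalue = 0, bitscore = 2 * nchar(cds[[id]]),
        stringsAsFactors = FALSE)
    }
    cmb <- utils::combn(ids, 2L)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      ca <- strsplit(cds[[a]], "")[[1]]; cb <- strsplit(cds[[b]], "")[[1]]
      pid <- 100 * mean(ca == cb)
      u5a <- regexpr(cds[[a]], unigene[[a]], fixed = TRUE)
      u5b <- regexpr(cds[[b]], unigene[[b]], fixed = TRUE)
      allbyall[[length(allbyall) + 1L]] <- data.frame(
        qid = a, sid = b, pident = round(pid, 2),
        aln_len = length(ca), mismatches = sum(ca != cb), gapopens = 0L,
        qstart = as.integer(u5a), qend = as.integer(u5a) + length(ca) - 1L,
        sstart = as.integer(u5b), send = as.integer(u5b) + length(cb) - 1L,
        evalue = 1e-50, bitscore = 2 * sum(ca == cb),
        stringsAsFactors = FALSE)
    }
  }
  paths <- list(
    unigenes = file.path(dir, "unigenes.fa"),
    protein_hits = file.path(dir, "protein_hits.tsv"),
    allbyall = file.path(dir, "allbyall.tsv"),
    proteins = file.path(dir, "proteins.fa"),
    ground_truth = file.path(dir, "ground_truth.json"))
  writeFasta(unigene, paths$unigenes)
  writeFasta(prot_seqs, paths$proteins)
  writeHits(do.call(rbind, prot_hits), paths$protein_hits)
  writeHits(do.call(rbind, allbyall), paths$allbyall)
  truth <- list(event_ks = event_ks,
                nodes = do.call(rbind, truth_nodes))
  jsonlite::write_json(truth, paths$ground_truth, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  c(paths, list(truth = truth, dir = dir))
}
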