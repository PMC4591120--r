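caln <- function(c1, c2) {
  tab <- ksdater:::codonTable()
  ksdater:::.caln_from_idx(match(c1, tab$codons), match(c2, tab$codons))
}

test_that("protein alignment reproduces known cases and is symmetric", {
  a <- alignProteins("MKVLL", "MKVLL")
  expect_equal(a$a, a$b)
  expect_false(grepl("-", a$a))

  a <- alignProteins("MKV", "MV")
  expect_equal(a$a, "MKV")
  expect_equal(a$b, "M-V")

  s1 <- alignProteins("MKVWYH", "MKWYH")$score
  s2 <- alignProteins("MKWYH", "MKVWYH")$score
  expect_equal(s1, s2)
})

test_that("back-translation preserves the residue-codon mapping", {
  ## no-gap case: concatenation of the original codons
  aln <- list(a = "MK", b = "MR")
  ca <- backTranslate(aln, "ATGAAA", "ATGAGA")
  expect_equal(ca$codons_a, c("ATG", "AAA"))
  expect_equal(ca$n_ungapped, 2L)

  ## gap row maps to --- and drops from the ungapped set
  aln <- list(a = "MKV", b = "M-V")
  ca <- backTranslate(aln, "ATGAAAGTT", "ATGGTG")
  expect_equal(ca$codons_b, c("ATG", "---", "GTG"))
  expect_equal(ca$n_ungapped, 2L)

  ## N-containing codons stay in n_cols but not n_ungapped
  aln <- list(a = "MK", b = "MX")
  ca <- backTranslate(aln, "ATGAAA", "ATGAAN")
  expect_equal(ca$n_cols, 2L)
  expect_equal(ca$n_ungapped, 1L)

  expect_error(backTranslate(list(a = "MK", b = "MK"), "ATGAAA", "ATG"),
               "cds_b")
})

test_that("NG86 matches the exhaustive oracle on random codon pairs", {
  set.seed(29)
  tab <- ksdater:::codonTable()
  for (r in 1:200) {
    cp <- random_sense_codon_pair()
    est <- ksdater:::ng86PairCounts(match(cp[1], tab$codons),
                                    match(cp[2], tab$codons))
    oracle <- oracle_pair_diffs(cp[1], cp[2])
    if (oracle[["n_paths"]] > 0) {
      expect_equal(est[["sd"]], oracle[["sd"]])
      expect_equal(est[["nd"]], oracle[["nd"]])
      expect_equal(est[["fallback"]], 0)
    } else if (cp[1] != cp[2]) {
      expect_equal(est[["fallback"]], 1)
    }
    ## site counts against the oracle, both codons
    expect_equal(tab$s_sites[match(cp[1], tab$codons)],
                 oracle_syn_sites(cp[1]))
  }
})

test_that("pathway step counts are conserved", {
  ## a 3-position difference always decomposes into exactly 3 steps
  set.seed(31)
  found <- 0
  while (found < 25) {
    cp <- random_sense_codon_pair()
    n_diff <- sum(strsplit(cp[1], "")[[1]] != strsplit(cp[2], "")[[1]])
    if (n_diff != 3) next
    o <- oracle_pair_diffs(cp[1], cp[2])
    if (o[["n_paths"]] == 0) next
    est <- ksNG86(caln(cp[1], cp[2]))
    expect_equal(est$Sd + est$Nd, 3)
    found <- found + 1
  }
})

test_that("identical sequences give zero distances under both methods", {
  cds <- randomCds(80, seed = 5)
  for (m in c("NG86", "YN00")) {
    r <- pairKs(cds, cds, m)
    expect_equal(r$ks, 0)
    expect_equal(r$ka, 0)
    expect_equal(r$Sd, 0)
    expect_equal(r$S + r$N, 3 * 80)
  }
})

test_that("estimators are symmetric in sequence order", {
  for (r in 1:5) {
    anc <- randomCds(120, seed = 40 + r)
    ep <- evolvePair(anc, 0.4, seed = 50 + r, calibrate = FALSE)
    for (m in c("NG86", "YN00")) {
      f <- pairKs(ep$a, ep$b, m, id_a = "x", id_b = "y")
      g <- pairKs(ep$b, ep$a, m, id_a = "y", id_b = "x")
      for (col in c("S", "N", "Sd", "Nd", "kappa", "ka", "ks")) {
        expect_lt(abs(f[[col]] - g[[col]]), 1e-12)
      }
    }
  }
})

test_that("YN00 reduces to NG86 site counts at kappa 1, uniform freqs", {
  set.seed(61)
  for (r in 1:15) {
    anc <- randomCds(100, seed = 600 + r)
    ep <- evolvePair(anc, runif(1, 0.05, 0.8), seed = 700 + r,
                     calibrate = FALSE)
    ng <- pairKs(ep$a, ep$b, "NG86")
    yn <- pairKs(ep$a, ep$b, "YN00", fix_kappa = 1, freqs = "uniform")
    expect_lt(abs(yn$S - ng$S), 1e-6)
    expect_lt(abs(yn$N - ng$N), 1e-6)
  }
})

test_that("estimates are monotone in planted divergence", {
  targets <- c(0.1, 0.3, 0.6)
  means <- vapply(targets, function(t) {
    est <- vapply(1:12, function(r) {
      anc <- randomCds(200, seed = 800 + r)
      ep <- evolvePair(anc, t, seed = 900 + 100 * t + r, calibrate = FALSE)
      pairKs(ep$a, ep$b, "NG86")$ks
    }, numeric(1))
    mean(est)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("purely synonymous evolution yields ka = 0", {
  anc <- randomCds(150, seed = 71)
  ep <- evolvePair(anc, 0.3, omega = 0, seed = 72, calibrate = FALSE)
  expect_equal(sum(ep$realized$nonsyn), 0L)
  for (m in c("NG86", "YN00")) {
    r <- pairKs(ep$a, ep$b, m)
    expect_equal(r$ka, 0)
    expect_gt(r$ks, 0)
  }
})

test_that("gap and N columns never contribute to counts", {
  ## same pair, with and without a disrupting N
  anc <- randomCds(60, seed = 81)
  ep <- evolvePair(anc, 0.2, seed = 82, calibrate = FALSE)
  base <- pairKs(ep$a, ep$b, "NG86")
  a_n <- paste0("AAN", substr(ep$a, 4, nchar(ep$a)))
  b_s <- paste0("AAA", substr(ep$b, 4, nchar(ep$b)))
  with_n <- pairKs(a_n, b_s, "NG86")
  expect_equal(with_n$S + with_n$N, 3 * 59)
})

test_that("saturated pairs are flagged, not clamped", {
  tab <- ksdater:::codonTable()
  set.seed(95)
  ## two unrelated random sequences: enormous divergence
  a <- randomCds(100, seed = 96)
  b <- randomCds(100, seed = 97)
  r <- pairKs(a, b, "NG86")
  if (is.na(r$ks)) expect_match(r$flags, "saturated_ks")
  expect_true(is.na(r$ks) || r$ks > 0.5)
})
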