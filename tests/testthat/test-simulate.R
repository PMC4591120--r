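test_that("random CDS generation is deterministic and stop-free", {
  a <- randomCds(100, seed = 3)
  b <- randomCds(100, seed = 3)
  expect_equal(a, b)
  expect_equal(nchar(a), 300L)
  expect_true(startsWith(a, "ATG"))
  codons <- substring(a, seq(1, 298, 3), seq(3, 300, 3))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  expect_false(identical(a, randomCds(100, seed = 4)))
})

test_that("zero divergence returns the ancestor unchanged", {
  anc <- randomCds(60, seed = 5)
  ep <- evolvePair(anc, 0, seed = 6)
  expect_equal(ep$a, anc)
  expect_equal(ep$b, anc)
  expect_equal(sum(ep$realized$syn), 0L)
})

test_that("evolved descendants stay in-frame and stop-free", {
  anc <- randomCds(120, seed = 7)
  ep <- evolvePair(anc, 0.8, seed = 8, calibrate = FALSE)
  for (s in c(ep$a, ep$b)) {
    expect_equal(nchar(s), nchar(anc))
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
  expect_gt(sum(ep$realized$syn), 0)
})

test_that("calibrated evolution recovers the target Ks in expectation", {
  target <- 0.25
  est <- vapply(1:60, function(r) {
    anc <- randomCds(300, seed = 1000 + r)
    ep <- evolvePair(anc, target, seed = 2000 + r)
    pairKs(ep$a, ep$b, "NG86")$ks
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - target), 4 * se + 0.002)
})

test_that("family evolution yields m - 1 sorted true node depths", {
  anc <- randomCds(100, seed = 11)
  fam <- evolveFamily(anc, c(0.9, 0.2, 0.5), seed = 12)
  expect_length(fam$leaves, 4L)
  expect_equal(fam$true_node_ks, c(0.2, 0.5, 0.9))
  expect_equal(names(fam$leaves), paste0("g", 1:4))
  expect_true(all(nchar(fam$leaves) == nchar(anc)))

  ## estimated node depths track the planted ones (coarsely, one family)
  cds <- Biostrings::DNAStringSet(fam$leaves)
  cmb <- utils::combn(names(cds), 2)
  pk <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    pairKs(cds[[cmb[1, k]]], cds[[cmb[2, k]]], "NG86",
           id_a = cmb[1, k], id_b = cmb[2, k])
  }))
  nd <- nodeKs(pk)
  expect_equal(nrow(nd), 3L)
  expect_true(all(abs(sort(nd$ks) - c(0.2, 0.5, 0.9)) < 0.25))
})

test_that("mixture sampling respects count, range, weights and medians", {
  v <- sampleKsMixture(c(0.7, 0.3), log(c(0.25, 1.33)), c(0.1, 0.1),
                       n = 529, seed = 31)
  expect_length(v, 529L)
  expect_true(all(v > 0 & v < 2))
  expect_equal(v, sampleKsMixture(c(0.7, 0.3), log(c(0.25, 1.33)),
                                  c(0.1, 0.1), n = 529, seed = 31))

  ## sigma = 0 collapses each component to its median
  v0 <- sampleKsMixture(c(0.5, 0.5), log(c(0.3, 1.2)), c(0, 0),
                        n = 100, seed = 32)
  expect_setequal(round(unique(v0), 10), round(c(0.3, 1.2), 10))

  ## large-sample component median within 1 percent
  v1 <- sampleKsMixture(1, log(0.25), 0.08, n = 10000, seed = 33)
  expect_lt(abs(median(v1) / 0.25 - 1), 0.01)

  expect_error(sampleKsMixture(c(0.6, 0.6), c(0, 0), c(1, 1)), "sum")
})

test_that("toy hit table ground truth matches an honest reading", {
  toy <- toyHitTable(seed = 2, n_random = 5)
  exp_pairs <- toy$expected_pairs
  ## planted cases: u1-u2 survives once, boundary row survives, failures out
  expect_true(any(exp_pairs$id_a == "u1" & exp_pairs$id_b == "u2"))
  expect_true(any(exp_pairs$id_a == "u5" & exp_pairs$id_b == "u6"))
  expect_false(any(exp_pairs$id_a == "u2" & exp_pairs$id_b == "u3"))
  expect_false(any(exp_pairs$id_a == "u3" & exp_pairs$id_b == "u4"))
  expect_false(any(exp_pairs$id_a == "u4" & exp_pairs$id_b == "u5"))
  expect_equal(nrow(exp_pairs), 3 + 5)

  ## round trip through disk and the package filter
  f <- withr::local_tempfile(fileext = ".tsv")
  toy <- toyHitTable(path = f, seed = 2, n_random = 5)
  got <- filterParalogPairs(readHits(f))
  expect_equal(got[, c("id_a", "id_b")], toy$expected_pairs)
})

test_that("a self-hit-only table leaves no pairs", {
  toy <- toyHitTable(seed = 3, n_random = 0)
  only_self <- toy$hits[toy$hits$qid == toy$hits$sid, , drop = FALSE]
  expect_equal(nrow(filterParalogPairs(only_self)), 0L)
})

test_that("simulated transcriptomes carry consistent files and truth", {
  dir <- withr::local_tempdir()
  sim <- simulateTranscriptome(n_young = 4, n_old = 3, n_both = 1,
                               n_codons = 80, dir = file.path(dir, "tx"),
                               seed = 5)
  expect_true(all(file.exists(unlist(sim[c(
    "unigenes", "protein_hits", "allbyall", "proteins", "ground_truth")]))))
  u <- readFasta(sim$unigenes, "nt")
  ## 4 + 3 two-member families and 1 three-member family
  expect_length(u, 2 * 7 + 3)
  expect_equal(nrow(sim$truth$nodes), 7 + 2)
  expect_equal(sim$truth$event_ks, c(0.25, 1.33))
  ## every unigene has a protein hit; spans map back to the unigene
  ph <- readHits(sim$protein_hits)
  expect_setequal(ph$qid, names(u))
  expect_true(all(ph$qend <= Biostrings::width(u)[match(ph$qid, names(u))]))
  ## truth node depths scatter around the events
  young <- sim$truth$nodes$node_ks[sim$truth$nodes$event == 1]
  expect_true(all(abs(log(young) - log(0.25)) < 4 * 0.08))
})
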