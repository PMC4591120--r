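toy_hit <- function(qid, sid, evalue = 1e-20, pident = 80, aln_len = 300) {
  data.frame(qid = qid, sid = sid, pident = pident,
             aln_len = as.integer(aln_len), mismatches = 0L, gapopens = 0L,
             qstart = 1L, qend = aln_len, sstart = 1L, send = aln_len,
             evalue = evalue, bitscore = 200, stringsAsFactors = FALSE)
}

test_that("paralog filter applies inclusive thresholds and merges pairs", {
  h <- rbind(
    toy_hit("a", "a"),                        # self-hit
    toy_hit("a", "b", evalue = 1e-5, pident = 40, aln_len = 150),  # boundary
    toy_hit("b", "a", evalue = 1e-7),         # reciprocal: merged
    toy_hit("a", "c", evalue = 2e-5),         # fails evalue
    toy_hit("c", "d", pident = 39.99),        # fails pident
    toy_hit("d", "e", aln_len = 149))         # fails length
  p <- filterParalogPairs(h)
  expect_equal(nrow(p), 1L)
  expect_equal(p$id_a, "a")
  expect_equal(p$id_b, "b")
  expect_equal(p$evalue, 1e-7)  # best supporting row kept
  expect_true(all(p$id_a < p$id_b))

  expect_equal(nrow(filterParalogPairs(h[0, , drop = FALSE])), 0L)
})

test_that("loosening any threshold never removes pairs", {
  set.seed(17)
  n <- 120
  h <- toy_hit(sprintf("g%03d", sample(60, n, TRUE)),
               sprintf("g%03d", sample(60, n, TRUE)),
               evalue = 10^-runif(n, 2, 40),
               pident = runif(n, 20, 100),
               aln_len = sample(50:600, n, TRUE))
  base <- filterParalogPairs(h)
  key <- function(p) paste(p$id_a, p$id_b)
  expect_true(all(key(base) %in%
                    key(filterParalogPairs(h, evalue_max = 1e-3))))
  expect_true(all(key(base) %in%
                    key(filterParalogPairs(h, pident_min = 20))))
  expect_true(all(key(base) %in%
                    key(filterParalogPairs(h, alnlen_min = 50))))
})

test_that("single linkage builds connected components", {
  pairs <- data.frame(id_a = c("a", "b", "x"), id_b = c("b", "c", "y"),
                      stringsAsFactors = FALSE)
  fam <- singleLinkageFamilies(pairs)
  mem <- attr(fam, "families")
  expect_length(mem, 2L)
  expect_equal(mem[[1]], c("a", "b", "c"))  # transitive closure
  expect_equal(mem[[2]], c("x", "y"))
  expect_equal(fam$family_id[fam$id == "c"], 1L)

  empty <- singleLinkageFamilies(pairs[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
  expect_length(attr(empty, "families"), 0L)
})

test_that("family pair Ks covers every member pair and keeps failures", {
  fam <- evolveFamily(randomCds(80, seed = 201), c(0.2, 0.6), seed = 202)
  cds <- Biostrings::DNAStringSet(fam$leaves)
  pairs <- data.frame(id_a = c("g1", "g2"), id_b = c("g2", "g3"),
                      stringsAsFactors = FALSE)
  fams <- singleLinkageFamilies(pairs)
  pk <- familyPairKs(fams, cds, "NG86")
  expect_equal(nrow(pk), choose(3, 2))
  expect_true(all(is.finite(pk$ks) | pk$ks == Inf))
})

test_that("node decomposition matches the hand example", {
  ## three genes, pair Ks {ab: 0.10, ac: 0.50, bc: 0.52}
  pk <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                   ks = c(0.10, 0.50, 0.52), ka = c(0.05, 0.2, 0.22),
                   stringsAsFactors = FALSE)
  nd <- nodeKs(pk)  # median summary
  expect_equal(nrow(nd), 2L)
  expect_equal(nd$ks, c(0.10, 0.51))   # median of {0.50, 0.52}
  expect_equal(nd$n_left + nd$n_right, c(2L, 3L))
  expect_true(all(nd$in_range))

  nd_min <- nodeKs(pk, summary = "min")
  expect_equal(nd_min$ks, c(0.10, 0.50))
  nd_mean <- nodeKs(pk, summary = "mean")
  expect_equal(nd_mean$ks[2], 0.51)
})

test_that("a family of m genes yields at most m - 1 node values", {
  set.seed(33)
  for (r in 1:20) {
    m <- sample(2:7, 1)
    ids <- letters[1:m]
    cmb <- utils::combn(ids, 2)
    pk <- data.frame(id_a = cmb[1, ], id_b = cmb[2, ],
                     ks = runif(ncol(cmb), 0.01, 1.9),
                     stringsAsFactors = FALSE)
    nd <- nodeKs(pk)
    expect_lte(nrow(nd), m - 1L)
    expect_gte(nrow(nd), 1L)
  }
})

test_that("zero-Ks nodes are removed and out-of-range nodes flagged", {
  pk <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                   ks = c(0, 2.5, 2.6), stringsAsFactors = FALSE)
  nd <- nodeKs(pk)
  expect_false(any(nd$ks == 0))
  expect_true(any(!nd$in_range))  # > 2 flagged out of range

  ## fully identical family contributes nothing
  pk0 <- data.frame(id_a = "a", id_b = "b", ks = 0)
  expect_equal(nrow(nodeKs(pk0)), 0L)
})

test_that("failed (Inf) pairs cannot set a finite node height alone", {
  pk <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                   ks = c(0.3, Inf, Inf), stringsAsFactors = FALSE)
  nd <- nodeKs(pk)
  expect_equal(nd$ks[1], 0.3)
  expect_false(is.finite(nd$ks[2]))
  expect_false(nd$in_range[2])
})

test_that("ultrametric distances are reproduced exactly by min linkage", {
  ## caterpillar truth: heights 0.2 (a,b) then 0.8 joining c
  pk <- data.frame(id_a = c("a", "a", "b"), id_b = c("b", "c", "c"),
                   ks = c(0.2, 0.8, 0.8), stringsAsFactors = FALSE)
  nd <- nodeKs(pk, summary = "min")
  expect_equal(nd$ks, c(0.2, 0.8))
  nd_med <- nodeKs(pk)  # median agrees when cross distances are equal
  expect_equal(nd_med$ks, c(0.2, 0.8))
})

test_that("allNodeKs stacks per-family blocks", {
  pk <- rbind(
    data.frame(family_id = 1L, id_a = "a", id_b = "b", ks = 0.4),
    data.frame(family_id = 2L, id_a = "x", id_b = "y", ks = 1.1))
  nd <- allNodeKs(pk)
  expect_equal(nd$family_id, c(1L, 2L))
  expect_equal(nd$ks, c(0.4, 1.1))
})
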