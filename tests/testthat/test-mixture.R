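test_that("histogram bins are half-open with exact boundary placement", {
  h <- ksHistogram(c(0.049, 0.050, 0.0999, 0.1, 1.999))
  expect_equal(h$bins$count[1], 1L)   # 0.049 in [0, 0.05)
  expect_equal(h$bins$count[2], 2L)   # 0.050 and 0.0999 in [0.05, 0.10)
  expect_equal(h$bins$count[3], 1L)   # 0.1 in [0.10, 0.15)
  expect_equal(h$bins$count[40], 1L)  # 1.999 in the last bin
  expect_equal(nrow(h$bins), 40L)
  expect_equal(sum(h$bins$count), 5L)

  expect_error(ksHistogram(c(0.5, 2.0)), "outside")
  expect_error(ksHistogram(0), "outside")
  expect_equal(sum(ksHistogram(numeric(0))$bins$count), 0L)
})

test_that("histogram conserves counts at realistic sample size", {
  set.seed(41)
  v <- sampleKsMixture(c(0.7, 0.3), log(c(0.25, 1.33)), c(0.25, 0.2),
                       n = 529, seed = 42)
  h <- ksHistogram(v)
  expect_equal(sum(h$bins$count), 529L)
  expect_equal(h$n, 529L)
})

test_that("K = 1 fit matches the closed-form normal MLE", {
  set.seed(51)
  v <- exp(rnorm(400, log(0.3), 0.3))
  v <- v[v > 0 & v < 2]
  fit <- fitKsMixture(v, 1, n_random_starts = 5, n_kmeans_starts = 2,
                      seed = 1)
  x <- log(v)
  expect_equal(componentMeans(fit), mean(x), tolerance = 1e-6)
  expect_equal(componentSigmas(fit),
               sqrt(mean((x - mean(x))^2)), tolerance = 1e-5)
  n <- length(x)
  ll <- sum(dnorm(x, mean(x), sqrt(mean((x - mean(x))^2)), log = TRUE))
  expect_equal(fit@loglik, ll, tolerance = 1e-6)
  expect_equal(modelAIC(fit), -2 * ll + 2 * 2, tolerance = 1e-4)
  expect_equal(modelBIC(fit), -2 * ll + 2 * log(n), tolerance = 1e-4)
})

test_that("EM log-likelihood trace is nondecreasing", {
  v <- sampleKsMixture(c(0.6, 0.4), log(c(0.25, 1.3)), c(0.15, 0.15),
                       n = 300, seed = 7)
  fit <- fitKsMixture(v, 2, n_random_starts = 10, n_kmeans_starts = 3,
                      seed = 3)
  tr <- fit@trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) >= -1e-8))
})

test_that("a richer model never has lower maximized log-likelihood", {
  v <- sampleKsMixture(c(0.6, 0.4), log(c(0.25, 1.3)), c(0.2, 0.2),
                       n = 350, seed = 9)
  sc <- ksMixtureScan(v, kmax = 3, n_random_starts = 30,
                      n_kmeans_starts = 5, seed = 5)
  ll <- sc$table$loglik
  expect_true(all(diff(ll) >= -1e-4))
})

test_that("BIC recovers K = 2 on well-separated two-component data", {
  v <- sampleKsMixture(c(0.65, 0.35), log(c(0.25, 1.33)), c(0.2, 0.15),
                       n = 500, seed = 11)
  sc <- ksMixtureScan(v, kmax = 4, n_random_starts = 30,
                      n_kmeans_starts = 5, seed = 13)
  expect_equal(sc$best_bic, 2L)
  mus <- componentMeans(sc$fits[["K2"]])
  expect_lt(abs(mus[1] - log(0.25)), 0.08)
  expect_lt(abs(mus[2] - log(1.33)), 0.08)
})

test_that("model selection breaks exact ties toward the smaller K", {
  mk <- function(K, ll) methods::new(
    "KsMixtureFit", K = as.integer(K), weights = rep(1 / K, K),
    mu = sort(rnorm(K)), sigma = rep(1, K), loglik = ll, n = 100L,
    aic = -2 * ll + 2 * (3 * K - 1), bic = -2 * ll + (3 * K - 1) * log(100),
    startLabel = "manual", converged = TRUE, trace = ll)
  set.seed(1)
  f1 <- mk(1, -50)
  ## pick loglik for K = 2 so BIC matches f1's exactly
  ll2 <- -50 + (3 * 2 - 1 - 2) * log(100) / 2
  f2 <- mk(2, ll2)
  sel <- selectMixtureModel(list(f1, f2))
  expect_equal(sel$table$bic[1], sel$table$bic[2], tolerance = 1e-10)
  expect_equal(sel$best_bic, 1L)
})

test_that("fits are invariant to the order of the input values", {
  v <- sampleKsMixture(c(0.5, 0.5), log(c(0.3, 1.2)), c(0.2, 0.2),
                       n = 200, seed = 21)
  f1 <- fitKsMixture(v, 2, n_random_starts = 10, n_kmeans_starts = 2,
                     seed = 8)
  f2 <- fitKsMixture(rev(v), 2, n_random_starts = 10, n_kmeans_starts = 2,
                     seed = 8)
  expect_equal(componentMeans(f1), componentMeans(f2))
  expect_equal(f1@loglik, f2@loglik)
})

test_that("fit invariants hold: weights sum to 1, mus ascend, validity", {
  v <- sampleKsMixture(c(0.4, 0.6), log(c(0.3, 1.2)), c(0.2, 0.2),
                       n = 250, seed = 23)
  fit <- fitKsMixture(v, 2, n_random_starts = 15, n_kmeans_starts = 3,
                      seed = 2)
  expect_equal(sum(mixtureWeights(fit)), 1, tolerance = 1e-9)
  expect_false(is.unsorted(componentMeans(fit)))
  expect_true(all(componentSigmas(fit) > 0))
  expect_true(methods::validObject(fit))
  expect_equal(nComponents(fit), 2L)
  expect_output(show(fit), "KsMixtureFit: 2 component")
})

test_that("guards reject unusable inputs", {
  expect_error(fitKsMixture(c(-0.1, 0.5, 0.6), 1), "positive")
  expect_error(fitKsMixture(c(0.1, 0.2), 1), "3K")
  expect_error(ksMixtureScan(c(0.1, 0.2), kmax = 2), "too few")
})
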