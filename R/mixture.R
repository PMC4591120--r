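#' KsMixtureFit: a normal mixture fitted to ln(Ks)
#'
#' Container for one K-component normal mixture fitted on the natural-log
#' scale of node-Ks values (normal components on ln Ks correspond to
#' lognormal components on the Ks scale). Free-parameter count is
#' p = 3K - 1 (K means, K standard deviations, K - 1 free weights);
#' AIC = -2 loglik + 2p and BIC = -2 loglik + p ln(n).
#'
#' @slot K Number of components.
#' @slot weights Mixing proportions (sum to 1).
#' @slot mu Component means on the ln scale, ascending.
#' @slot sigma Component standard deviations on the ln scale.
#' @slot loglik Log-likelihood of the best start.
#' @slot n Sample size.
#' @slot aic,bic Information criteria.
#' @slot startLabel Which start won (e.g. "random-37", "kmeans-3").
#' @slot converged Whether that start converged within the iteration cap.
#' @slot trace Log-likelihood per EM iteration of the winning start.
#' @export
setClass("KsMixtureFit", representation(
  K = "integer", weights = "numeric", mu = "numeric", sigma = "numeric",
  loglik = "numeric", n = "integer", aic = "numeric", bic = "numeric",
  startLabel = "character", converged = "logical", trace = "numeric"))

setValidity("KsMixtureFit", function(object) {
  msgs <- character(0)
  if (length(object@weights) != object@K ||
      length(object@mu) != object@K ||
      length(object@sigma) != object@K)
    msgs <- c(msgs, "weights, mu, sigma must each have length K")
  if (abs(sum(object@weights) - 1) > 1e-9)
    msgs <- c(msgs, "weights must sum to 1")
  if (any(object@weights < 1e-8))
    msgs <- c(msgs, "weights must be >= 1e-8")
  if (any(object@sigma <= 0))
    msgs <- c(msgs, "sigmas must be positive")
  if (is.unsorted(object@mu))
    msgs <- c(msgs, "components must be sorted by mu")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn KsMixtureFit Number of components.
#' @param object A `KsMixtureFit`.
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
#' @rdname KsMixtureFit
#' @export
setMethod("nComponents", "KsMixtureFit", function(object) object@K)

#' @rdname KsMixtureFit
#' @export
setGeneric("mixtureWeights", function(object) standardGeneric("mixtureWeights"))
#' @rdname KsMixtureFit
#' @export
setMethod("mixtureWeights", "KsMixtureFit", function(object) object@weights)

#' @rdname KsMixtureFit
#' @export
setGeneric("componentMeans", function(object) standardGeneric("componentMeans"))
#' @rdname KsMixtureFit
#' @export
setMethod("componentMeans", "KsMixtureFit", function(object) object@mu)

#' @rdname KsMixtureFit
#' @export
setGeneric("componentSigmas", function(object) standardGeneric("componentSigmas"))
#' @rdname KsMixtureFit
#' @export
setMethod("componentSigmas", "KsMixtureFit", function(object) object@sigma)

#' @rdname KsMixtureFit
#' @export
setGeneric("modelAIC", function(object) standardGeneric("modelAIC"))
#' @rdname KsMixtureFit
#' @export
setMethod("modelAIC", "KsMixtureFit", function(object) object@aic)

#' @rdname KsMixtureFit
#' @export
setGeneric("modelBIC", function(object) standardGeneric("modelBIC"))
#' @rdname KsMixtureFit
#' @export
setMethod("modelBIC", "KsMixtureFit", function(object) object@bic)

setMethod("show", "KsMixtureFit", function(object) {
  cat(sprintf(
    "KsMixtureFit: %d component(s) on ln(Ks), n = %d (start %s%s)\n",
    object@K, object@n, object@startLabel,
    if (object@converged) "" else ", NOT converged"))
  cat(sprintf("  loglik %.3f  AIC %.2f  BIC %.2f\n",
              object@loglik, object@aic, object@bic))
  for (k in seq_len(object@K)) {
    cat(sprintf(
      "  comp %d: weight %.3f, mu %.3f (sd %.3f), median Ks %.3f\n",
      k, object@weights[k], object@mu[k], object@sigma[k],
      exp(object@mu[k])))
  }
  invisible(NULL)
})

#' Node-Ks age-distribution histogram
#'
#' Bins Ks values into half-open intervals `[low, high)` of width
#' `bin_width` over `range` (defaults: 0.05 over \code{[0, 2)}, i.e. 40
#' bins). Values outside the open interval (0, 2) are a hard error: range
#' filtering is the caller's contract.
#'
#' @param values Ks values in (0, 2).
#' @param bin_width Bin width.
#' @param range Two-element numeric range.
#' @return List of class `ksd_ks_histogram`: `bins` (data.frame bin_low,
#'   bin_high, count), `bin_width`, `range`, `n`.
#' @export
ksHistogram <- function(values, bin_width = 0.05, range = c(0, 2)) {
  if (length(values) &&
      (any(values <= range[1]) || any(values >= range[2])))
    stop("Ks value outside (", range[1], ", ", range[2],
         "): filter upstream")
  n_bins <- as.integer(round(diff(range) / bin_width))
  breaks <- range[1] + bin_width * (0:n_bins)
  idx <- if (length(values)) findInterval(values, breaks) else integer(0)
  counts <- tabulate(idx, nbins = n_bins)
  lows <- breaks[seq_len(n_bins)]
  structure(list(
    bins = data.frame(bin_low = lows, bin_high = lows + bin_width,
                      count = counts),
    bin_width = bin_width, range = range, n = length(values)),
    class = "ksd_ks_histogram")
}

#' @export
print.ksd_ks_histogram <- function(x, ...) {
  cat(sprintf("Ks histogram: %d values, %d bins of width %g over [%g, %g)\n",
              x$n, nrow(x$bins), x$bin_width, x$range[1], x$range[2]))
  invisible(x)
}

## One EM run from a given start. Returns list(weights, mu, sigma, loglik,
## converged, trace, degenerate).
.em_run <- function(x, K, w0, mu0, sigma0, tol = 1e-8, max_iter = 1000L,
                    var_floor = 1e-4, weight_floor = 1e-8) {
  n <- length(x)
  w <- w0; mu <- mu0; sigma <- pmax(sigma0, sqrt(var_floor))
  loglik <- -Inf; trace <- numeric(0); converged <- FALSE
  degenerate <- FALSE
  for (it in seq_len(max_iter)) {
    ## E-step in log space for stability
    logd <- vapply(seq_len(K), function(k) {
      stats::dnorm(x, mu[k], sigma[k], log = TRUE) + log(w[k])
    }, numeric(n))
    if (K == 1L) logd <- matrix(logd, ncol = 1L)
    m <- apply(logd, 1L, max)
    lse <- m + log(rowSums(exp(logd - m)))
    new_ll <- sum(lse)
    trace <- c(trace, new_ll)
    resp <- exp(logd - lse)
    ## M-step
    nk <- colSums(resp)
    w <- nk / n
    if (any(w < weight_floor)) { degenerate <- TRUE; break }
    mu <- colSums(resp * x) / nk
    v <- colSums(resp * (x - rep(mu, each = n))^2) / nk
    floored <- v < var_floor
    if (any(floored & w < 1e-6)) { degenerate <- TRUE; break }
    sigma <- sqrt(pmax(v, var_floor))
    if (is.finite(loglik) &&
        (new_ll - loglik) < tol * abs(loglik)) {
      converged <- TRUE
      loglik <- new_ll
      break
    }
    loglik <- new_ll
  }
  list(weights = w, mu = mu, sigma = sigma, loglik = loglik,
       converged = converged, trace = trace, degenerate = degenerate)
}

#' Fit a K-component normal mixture to ln(Ks) by multi-start EM
#'
#' Values are log-transformed internally; EM maximises the mixture
#' likelihood with `n_random_starts` random starts (component means drawn
#' from sample quantiles with jitter) and `n_kmeans_starts` k-means starts
#' (Lloyd's algorithm partitions the ln values and cluster moments seed the
#' EM). The best converged start is returned with components sorted by
#' mean. One seed controls all starts; start-level seeds are
#' `seed + start index`.
#'
#' @param values Ks values, all in (0, 2) and > 0.
#' @param K Number of components.
#' @param n_random_starts,n_kmeans_starts Start counts (defaults 100 and 10).
#' @param seed Integer seed governing every start.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per start.
#' @return A [KsMixtureFit-class] object.
#' @export
fitKsMixture <- function(values, K, n_random_starts = 100L,
                         n_kmeans_starts = 10L, seed = 1L,
                         tol = 1e-8, max_iter = 1000L) {
  if (any(values <= 0)) stop("Ks values must be positive")
  n <- length(values)
  K <- as.integer(K)
  if (n < 3L * K)
    stop("need at least 3K observations (n = ", n, ", K = ", K, ")")
  x <- sort(log(values))  # sorting makes fits order-independent
  sx <- stats::sd(x)
  if (!is.finite(sx) || sx == 0) sx <- 1e-2

  best <- NULL; best_label <- NA_character_
  run_start <- function(w0, mu0, sigma0, label) {
    res <- .em_run(x, K, w0, mu0, sigma0, tol = tol, max_iter = max_iter)
    if (!res$degenerate &&
        (is.null(best) || res$loglik > best$loglik)) {
      best <<- res; best_label <<- label
    }
  }
  for (i in seq_len(n_random_starts)) {
    set.seed(seed + i)
    probs <- sort(stats::runif(K))
    mu0 <- as.numeric(stats::quantile(x, probs)) +
      stats::rnorm(K, 0, 0.1 * sx)
    run_start(rep(1 / K, K), mu0, rep(sx, K), paste0("random-", i))
  }
  for (i in seq_len(n_kmeans_starts)) {
    set.seed(seed + n_random_starts + i)
    km <- tryCatch(
      stats::kmeans(x, centers = K, algorithm = "Lloyd", iter.max = 50L,
                    nstart = 1L),
      error = function(e) NULL)
    if (is.null(km)) next
    mu0 <- as.numeric(km$centers)
    sigma0 <- vapply(seq_len(K), function(k) {
      xs <- x[km$cluster == k]
      s <- if (length(xs) > 1L) stats::sd(xs) else sx
      max(s, 1e-2, na.rm = TRUE)
    }, numeric(1))
    w0 <- pmax(as.numeric(table(factor(km$cluster, levels = seq_len(K)))) / n,
               1e-3)
    w0 <- w0 / sum(w0)
    run_start(w0, mu0, sigma0, paste0("kmeans-", i))
  }
  if (is.null(best))
    stop("all EM starts degenerate; try a smaller K")
  ord <- order(best$mu)
  p <- 3 * K - 1
  methods::new("KsMixtureFit",
               K = K, weights = best$weights[ord], mu = best$mu[ord],
               sigma = best$sigma[ord], loglik = best$loglik,
               n = as.integer(n),
               aic = -2 * best$loglik + 2 * p,
               bic = -2 * best$loglik + p * log(n),
               startLabel = best_label, converged = best$converged,
               trace = best$trace)
}

#' Fit mixtures over a range of K and select by BIC/AIC
#'
#' Fits K = 1..`kmax` (skipping K with n < 3K) and selects the best model
#' by each criterion, ties broken toward smaller K.
#'
#' @param values Ks values in (0, 2).
#' @param kmax Largest component count to try.
#' @param ... Passed to [fitKsMixture()] (seed, start counts, ...).
#' @return List of class `ksd_mixture_scan`: `fits` (list of
#'   [KsMixtureFit-class]), `table` (data.frame K, loglik, p, aic, bic),
#'   `best_bic`, `best_aic` (selected K).
#' @export
ksMixtureScan <- function(values, kmax = 10L, ...) {
  ks <- seq_len(kmax)
  ks <- ks[length(values) >= 3L * ks]
  if (!length(ks)) stop("too few values to fit any mixture")
  fits <- lapply(ks, function(K) fitKsMixture(values, K, ...))
  names(fits) <- paste0("K", ks)
  sel <- selectMixtureModel(fits)
  structure(list(fits = fits, table = sel$table,
                 best_bic = sel$best_bic, best_aic = sel$best_aic),
            class = "ksd_mixture_scan")
}

#' @export
print.ksd_mixture_scan <- function(x, ...) {
  cat("Mixture scan over K:\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Selected: K = %d (BIC), K = %d (AIC)\n",
              x$best_bic, x$best_aic))
  invisible(x)
}

#' Select the best mixture by BIC and AIC
#'
#' @param fits List of [KsMixtureFit-class] objects (>= 2 for a real
#'   comparison).
#' @return List: `best_bic`, `best_aic` (the selected K values) and
#'   `table` (K, loglik, p, aic, bic). Ties go to the smaller K.
#' @export
selectMixtureModel <- function(fits) {
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(K = f@K, loglik = f@loglik, p = 3 * f@K - 1,
               aic = f@aic, bic = f@bic)
  }))
  tab <- tab[order(tab$K), , drop = FALSE]
  rownames(tab) <- NULL
  list(best_bic = tab$K[which.min(tab$bic)],
       best_aic = tab$K[which.min(tab$aic)],
       table = tab)
}

#' Summarise mixture components on the Ks scale
#'
#' Back-transforms each ln-scale component mean to the median of the
#' corresponding lognormal (median Ks = exp(mu)) and labels components
#' whose ln-scale standard deviation exceeds `sigma_background_threshold`
#' as `background` (continuous small-scale duplication across time) versus
#' `discrete-event` (a candidate WGD peak). Labels are descriptive
#' metadata; nothing is filtered. Discrete-event components additionally
#' get a divergence time from [dateEvent()].
#'
#' @param fit A [KsMixtureFit-class].
#' @param sigma_background_threshold Ln-scale sd above which a component is
#'   labeled background.
#' @param rate Synonymous substitution rate per site per year for dating.
#' @return Data.frame: component, weight, mu, sigma, median_ks, label,
#'   divergence_mya (NA for background components).
#' @export
summarizeComponents <- function(fit, sigma_background_threshold = 0.4,
                                rate = 6.1e-9) {
  mu <- componentMeans(fit); sigma <- componentSigmas(fit)
  label <- ifelse(sigma > sigma_background_threshold, "background",
                  "discrete-event")
  median_ks <- exp(mu)
  mya <- ifelse(label == "discrete-event",
                vapply(median_ks, dateEvent, numeric(1), rate = rate),
                NA_real_)
  data.frame(component = seq_along(mu), weight = mixtureWeights(fit),
             mu = mu, sigma = sigma, median_ks = median_ks,
             label = label, divergence_mya = mya,
             stringsAsFactors = FALSE)
}
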