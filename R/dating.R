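#' Date a duplication event from its median Ks
#'
#' Converts a Ks-peak location to an absolute divergence time with a
#' synonymous molecular clock: T = median_ks / (2 r) years, where r is the
#' synonymous substitution rate per site per year (default 6.1e-9, an
#' angiosperm average) and the divisor 2 accounts for the two lineages
#' accumulating substitutions independently since the duplication. The
#' result is returned in millions of years (Mya), unrounded; reports round
#' to one decimal.
#'
#' @param median_ks Median Ks of the component (> 0).
#' @param rate Synonymous substitution rate per synonymous site per year.
#' @return Divergence time in Mya (numeric, unrounded).
#' @export
dateEvent <- function(median_ks, rate = 6.1e-9) {
  if (!is.finite(median_ks) || median_ks <= 0)
    stop("median_ks must be a positive finite number")
  if (rate <= 0) stop("rate must be > 0")
  median_ks / (2 * rate) / 1e6
}

#' Date all discrete-event components of a mixture fit
#'
#' @param fit A [KsMixtureFit-class].
#' @param rate Clock rate (substitutions per synonymous site per year).
#' @param sigma_background_threshold Passed to [summarizeComponents()].
#' @param round_digits Decimal places of Mya in the report column.
#' @return Data.frame: component, weight, mu, sigma, median_ks, label,
#'   divergence_mya (unrounded), divergence_mya_report (rounded).
#' @export
dateWgdEvents <- function(fit, rate = 6.1e-9,
                          sigma_background_threshold = 0.4,
                          round_digits = 1L) {
  sm <- summarizeComponents(fit, sigma_background_threshold, rate = rate)
  sm$divergence_mya_report <- round(sm$divergence_mya, round_digits)
  sm
}
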