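## qPCR validation statistics: the background/enrichment call and
## ChIP-seq vs qPCR agreement.

#' qPCR background level from negative-control regions
#'
#' Background is the mean of the negative-region values plus two standard
#' deviations. The sample (n-1) SD is the default; set `population = TRUE`
#' for the n divisor.
#'
#' @param measurements Either a numeric vector of negative-control values,
#'   or a data.frame with `value` and logical `is_negative` columns (the
#'   negatives are extracted).
#' @param population Use the population SD (default `FALSE`).
#' @return Numeric background level.
#' @export
qpcr_background <- function(measurements, population = FALSE) {
  neg <- if (is.data.frame(measurements)) {
    measurements$value[as.logical(measurements$is_negative)]
  } else {
    as.numeric(measurements)
  }
  if (length(neg) < 2) stop("need >= 2 negative-control measurements")
  s <- stats::sd(neg)
  if (population) s <- s * sqrt((length(neg) - 1) / length(neg))
  mean(neg) + 2 * s
}

#' Call qPCR enrichment against a background level
#'
#' A region is positive when its value is strictly more than two-fold above
#' the background.
#'
#' @param value Numeric vector of qPCR enrichment values.
#' @param background Background level from [qpcr_background()].
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
qpcr_call <- function(value, background) {
  if (!is.finite(background) || background <= 0) {
    stop("background must be a positive number")
  }
  ifelse(value > 2 * background, "positive", "negative")
}

#' Squared Pearson correlation between ChIP-seq and qPCR enrichment
#'
#' @param chipseq_heights,qpcr_values Paired numeric vectors (length >= 3).
#' @return R-squared in `[0, 1]`, or `NA` when either vector has zero
#'   variance.
#' @export
agreement_r2 <- function(chipseq_heights, qpcr_values) {
  stopifnot(length(chipseq_heights) == length(qpcr_values))
  if (length(chipseq_heights) < 3) stop("need >= 3 paired measurements")
  if (stats::sd(chipseq_heights) == 0 || stats::sd(qpcr_values) == 0) {
    return(NA_real_)
  }
  stats::cor(chipseq_heights, qpcr_values)^2
}
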