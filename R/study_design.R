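#' Normal-approximation sample size for estimating a rate
#'
#' Implements the design formula `n = u_alpha^2 * sigma^2 / delta^2`, where
#' `u_alpha` is the two-sided standard-normal quantile at level `alpha`,
#' `sigma` the assumed standard deviation (in percentage points) and `delta`
#' the allowable error (same units). The result is rounded up, as sample
#' sizes conventionally are.
#'
#' The CIHD study design uses `sigma = 21.962` (a misdiagnosis-rate SD, in
#' percentage points) and `delta = 4` at `alpha = 0.05`, giving n = 116;
#' with the rounded quantile 1.96 the same 116 results.
#'
#' @param sigma assumed SD, percentage points (> 0).
#' @param delta allowable error, percentage points (> 0).
#' @param alpha two-sided significance level (used when `u_alpha` is not
#'   given).
#' @param u_alpha the normal quantile to use; defaults to
#'   `qnorm(1 - alpha/2)`, pass `1.96` for the conventional rounded value.
#' @return integer sample size, `ceiling(u_alpha^2 sigma^2 / delta^2)`.
#' @examples
#' required_n(sigma = 21.962, delta = 4, u_alpha = 1.96)   # 116
#' required_n(sigma = 21.962, delta = 4)                   # also 116
#' @export
required_n <- function(sigma, delta, alpha = 0.05,
                       u_alpha = qnorm(1 - alpha / 2)) {
  if (sigma <= 0 || delta <= 0 || u_alpha <= 0) {
    stop("sigma, delta and u_alpha must be strictly positive", call. = FALSE)
  }
  as.integer(ceiling(u_alpha^2 * sigma^2 / delta^2))
}

#' Scale a base rate by an expected fraction
#'
#' The design's effect-size step: multiplies a base rate (in percentage
#' points) by the fraction of it taken as the detectable effect, e.g.
#' `21.962% * 0.2 = 4.3924%`.
#'
#' @param base_rate_pct base rate in percentage points (>= 0).
#' @param fraction fraction in (0, 1].
#' @return the product, in percentage points.
#' @examples
#' effect_rate(21.962, 0.2)   # 4.3924
#' @export
effect_rate <- function(base_rate_pct, fraction) {
  stopifnot(base_rate_pct >= 0, fraction > 0, fraction <= 1)
  base_rate_pct * fraction
}
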