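#' Statistical moment features of an RR series
#'
#' RMS, variance, skewness, kurtosis and a bounded smoothness index. Moments
#' are population (1/N) by default. Kurtosis follows the Pearson convention
#' (Gaussian = 3, not excess). Smoothness is `1 - 1/(1 + Var_ms)` where
#' `Var_ms` is the variance of the series expressed in milliseconds; at
#' typical RR variability (SD of tens of ms) this saturates near 1, and the
#' millisecond scaling is explicit via `smoothness_scale`.
#'
#' @param s an [rr_series] or numeric vector (seconds).
#' @param type `"population"` or `"sample"` moments.
#' @param smoothness_scale multiplier applied before the smoothness variance
#'   (default 1000: seconds -> milliseconds).
#' @return named numeric vector `RMS`, `Var`, `Skewness`, `Kurtosis`,
#'   `Smoothness`. With zero variance, skewness and kurtosis are reported as
#'   0 with a warning.
#' @export
stat_features <- function(s, type = "population", smoothness_scale = 1000) {
  x <- as_intervals(s)
  if (length(x) < 4) stop("insufficient data", call. = FALSE)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (type == "sample") v <- stats::var(x) else v <- m2
  if (m2 <= 0) {
    warning("zero variance: skewness and kurtosis reported as 0",
            call. = FALSE)
    skew <- 0; kurt <- 0
  } else {
    skew <- mean(d^3) / m2^1.5
    kurt <- mean(d^4) / m2^2
  }
  v_ms <- v * smoothness_scale^2
  c(RMS = sqrt(mean(x^2)), Var = v, Skewness = skew, Kurtosis = kurt,
    Smoothness = 1 - 1 / (1 + v_ms))
}
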