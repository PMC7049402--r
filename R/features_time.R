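#' @importFrom stats sd var
NULL

# Population (1/N) moments are the package-wide convention; the sample
# (1/(N-1)) variant is available everywhere via type = "sample".
moment_sd <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  if (type == "sample") return(stats::sd(x))
  sqrt(mean((x - mean(x))^2))
}

as_intervals <- function(s) {
  if (inherits(s, "rr_series")) s$intervals else as.numeric(s)
}

#' SDNN: standard deviation of all RR intervals
#'
#' The workhorse global HRV index; depressed SDNN is the classic marker of
#' reduced variability in heart failure.
#'
#' @param s an [rr_series] or numeric vector of intervals (seconds).
#' @param type `"population"` (1/N, default) or `"sample"` (1/(N-1)) moments.
#' @return seconds.
#' @export
sdnn <- function(s, type = "population") {
  x <- as_intervals(s)
  if (length(x) < 2) stop("insufficient data", call. = FALSE)
  moment_sd(x, type)
}

#' SDANN: standard deviation of windowed mean RR
#'
#' The series is tiled into consecutive windows of `window_s` seconds on the
#' cumulative-time axis (5 minutes by convention), the mean RR of each
#' complete window is taken, and the standard deviation of those means is
#' returned. A trailing partial window is dropped.
#'
#' @inheritParams sdnn
#' @param window_s window length in seconds (default 300).
#' @return seconds.
#' @export
sdann <- function(s, window_s = 300, type = "population") {
  stopifnot(inherits(s, "rr_series"))
  total <- sum(s$intervals)
  if (total < 2 * window_s) stop("insufficient duration", call. = FALSE)
  win <- floor(s$t / window_s)
  n_complete <- floor(total / window_s)
  keep <- win < n_complete
  means <- tapply(s$intervals[keep], win[keep], mean)
  if (length(means) < 2) stop("insufficient duration", call. = FALSE)
  moment_sd(as.numeric(means), type)
}

#' RMSSD: root mean square of successive RR differences
#'
#' @inheritParams sdnn
#' @return seconds.
#' @export
rmssd <- function(s) {
  x <- as_intervals(s)
  if (length(x) < 3) stop("insufficient data", call. = FALSE)
  sqrt(mean(diff(x)^2))
}

#' SDSD: standard deviation of successive RR differences
#'
#' @inheritParams sdnn
#' @return seconds.
#' @export
sdsd <- function(s, type = "population") {
  x <- as_intervals(s)
  if (length(x) < 3) stop("insufficient data", call. = FALSE)
  moment_sd(diff(x), type)
}

#' All time-domain features of a series
#'
#' @inheritParams sdann
#' @return named numeric vector `SDANN`, `SDNN`, `SDSD`, `RMSSD` (seconds).
#' @export
time_features <- function(s, window_s = 300, type = "population") {
  c(SDANN = sdann(s, window_s, type), SDNN = sdnn(s, type),
    SDSD = sdsd(s, type), RMSSD = rmssd(s))
}
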