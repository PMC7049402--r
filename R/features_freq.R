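#' HRV frequency band scheme
#'
#' The standard task-force band edges: ULF up to 0.003 Hz, VLF 0.003-0.04 Hz,
#' LF 0.04-0.15 Hz, HF 0.15-0.40 Hz. Bands must be contiguous and
#' non-overlapping; a spectral bin at frequency f belongs to the band with
#' `f_low < f <= f_high`, so the four bands partition (0, f_max] and total
#' power is exactly the sum of the band powers.
#'
#' @param ulf,vlf,lf,hf numeric length-2 vectors `c(f_low, f_high)` in Hz.
#' @return data.frame with columns `band`, `f_low`, `f_high`; attribute
#'   `f_max`.
#' @export
band_scheme <- function(ulf = c(0, 0.003), vlf = c(0.003, 0.04),
                        lf = c(0.04, 0.15), hf = c(0.15, 0.40)) {
  b <- rbind(ulf, vlf, lf, hf)
  sch <- data.frame(band = c("ULF", "VLF", "LF", "HF"),
                    f_low = b[, 1], f_high = b[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(sch$f_low >= sch$f_high) || sch$f_low[1] < 0)
    stop("band edges must satisfy 0 <= f_low < f_high", call. = FALSE)
  if (any(abs(sch$f_high[-4] - sch$f_low[-1]) > 1e-12))
    stop("bands must be contiguous", call. = FALSE)
  attr(sch, "f_max") <- sch$f_high[4]
  sch
}

# one-sided Welch PSD via segment-averaged Hann-windowed periodograms
welch_psd <- function(y, fs, nper = 1024, overlap = 0.5) {
  n <- length(y)
  nper <- min(nper, n)
  step <- max(1, floor(nper * (1 - overlap)))
  starts <- seq(1, n - nper + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  U <- sum(w^2)
  acc <- numeric(nper %/% 2 + 1)
  for (s0 in starts) {
    seg <- y[s0:(s0 + nper - 1)]
    seg <- (seg - mean(seg)) * w
    ft <- stats::fft(seg)
    p <- Mod(ft[seq_len(nper %/% 2 + 1)])^2 / (fs * U)
    p[c(-1, -length(p))] <- 2 * p[c(-1, -length(p))]  # one-sided
    acc <- acc + p
  }
  list(freq = (seq_len(nper %/% 2 + 1) - 1) * fs / nper,
       psd = acc / length(starts))
}

#' Spectral band powers of an RR series
#'
#' Estimates the power spectral density of the mean-centred tachogram on its
#' cumulative-time axis and integrates it over the scheme's bands. The
#' default estimator is the Lomb-Scargle periodogram, which handles the
#' uneven beat-time sampling directly; the alternative cubic-spline resamples
#' the tachogram at `resample_hz` and applies Welch's method. Powers are
#' reported in consistent (arbitrary) units; only ratios and contrasts are
#' interpreted.
#'
#' @param s an [rr_series].
#' @param scheme a [band_scheme()].
#' @param method `"lomb"` (default) or `"resample_welch"`.
#' @param oversample frequency oversampling factor of the Lomb grid relative
#'   to the natural resolution 1/T.
#' @param resample_hz resampling rate for the Welch path, Hz.
#' @return named numeric vector `TP`, `ULF`, `VLF`, `LF`, `HF`, `LFHF`.
#'   `LFHF` is `Inf` (with a warning) when HF power is zero.
#' @export
band_powers <- function(s, scheme = band_scheme(),
                        method = c("lomb", "resample_welch"),
                        oversample = 1, resample_hz = 4) {
  method <- match.arg(method)
  stopifnot(inherits(s, "rr_series"))
  x <- s$intervals
  if (length(x) < 64) stop("insufficient data", call. = FALSE)
  f_max <- attr(scheme, "f_max")
  y <- x - mean(x)

  if (all(abs(y) < 1e-15)) {
    pw <- c(TP = 0, ULF = 0, VLF = 0, LF = 0, HF = 0)
  } else if (method == "lomb") {
    span <- max(s$t) - min(s$t)
    df <- 1 / (span * oversample)
    nf <- max(1L, floor(f_max / df))
    p <- .lomb_power(s$t, y, df, df, nf)
    freq <- df * seq_len(nf)
    pw <- integrate_bands(freq, p * df, scheme)
  } else {
    tt <- seq(0, max(s$t), by = 1 / resample_hz)
    yr <- stats::spline(s$t, x, xout = tt)$y
    yr <- stats::lm.fit(cbind(1, tt), yr)$residuals  # linear detrend
    ps <- welch_psd(yr, resample_hz)
    dfw <- ps$freq[2] - ps$freq[1]
    pw <- integrate_bands(ps$freq, ps$psd * dfw, scheme)
  }
  if (pw[["HF"]] == 0) {
    warning("HF power is zero; LFHF reported as Inf", call. = FALSE)
    lfhf <- Inf
  } else lfhf <- pw[["LF"]] / pw[["HF"]]
  c(pw, LFHF = lfhf)
}

integrate_bands <- function(freq, mass, scheme) {
  out <- numeric(4)
  names(out) <- scheme$band
  for (i in seq_len(4)) {
    sel <- freq > scheme$f_low[i] & freq <= scheme$f_high[i]
    out[i] <- sum(mass[sel])
  }
  c(TP = sum(out), out)
}

#' All frequency-domain features of a series
#'
#' @inheritParams band_powers
#' @return named numeric vector `TP`, `ULF`, `VLF`, `LF`, `HF`, `LFHF`.
#' @export
frequency_features <- function(s, scheme = band_scheme(), method = "lomb") {
  band_powers(s, scheme, method)
}
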