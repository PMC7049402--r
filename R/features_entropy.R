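#' Template-matching entropy parameters
#'
#' Embedding dimension `m = 3` and tolerance `r = 0.15 * SD(x)` are the
#' defaults used throughout the package for both approximate and sample
#' entropy. `r_floor` guards the degenerate case of a (near-)constant series
#' whose SD is zero, where a strictly zero tolerance would make every
#' template-match count ill-defined.
#'
#' @param m embedding (template) dimension, >= 1.
#' @param r_coeff tolerance as a multiple of the series SD.
#' @param r_floor absolute minimum tolerance.
#' @return list of class `entropy_params`.
#' @export
entropy_params <- function(m = 3, r_coeff = 0.15, r_floor = 1e-12) {
  if (m < 1 || r_coeff <= 0 || r_floor < 0)
    stop("invalid entropy parameters", call. = FALSE)
  structure(list(m = as.integer(m), r_coeff = r_coeff, r_floor = r_floor),
            class = "entropy_params")
}

tolerance_r <- function(x, p) max(p$r_coeff * moment_sd(x), p$r_floor)

# delay embedding, one template per row (column time-order irrelevant for
# the Chebyshev metric)
embed_templates <- function(x, m) {
  if (m == 1) matrix(x, ncol = 1) else stats::embed(x, m)
}

#' Approximate entropy (ApEn)
#'
#' Pincus' regularity statistic `Phi^m(r) - Phi^(m+1)(r)`, where `Phi^m(r)`
#' is the average log-frequency with which length-m templates recur within
#' Chebyshev tolerance r, self-matches included. Low values indicate a
#' regular, predictable series. Match counting uses the same KD-tree range
#' counter as [sampen_kdtree()]; the statistic is identical to the direct
#' O(N^2) count.
#'
#' @param x numeric vector or [rr_series].
#' @param p an [entropy_params()].
#' @return dimensionless entropy value.
#' @export
apen <- function(x, p = entropy_params()) {
  x <- as_intervals(x)
  n <- length(x)
  if (n < p$m + 2) stop("insufficient data", call. = FALSE)
  r <- tolerance_r(x, p)
  cm <- .cheb_range_counts(embed_templates(x, p$m), r)
  cm1 <- .cheb_range_counts(embed_templates(x, p$m + 1), r)
  mean(log(cm / length(cm))) - mean(log(cm1 / length(cm1)))
}

sampen_from_counts <- function(cm, cm1) {
  nt <- length(cm)
  B <- (sum(cm) - nt) / 2    # self-matches removed, pairs i<j
  A <- (sum(cm1) - nt) / 2
  if (A == 0 || B == 0) {
    warning("no template matches; SampEn reported as Inf", call. = FALSE)
    return(Inf)
  }
  -log(A / B)
}

#' Sample entropy, direct O(N^2) counting
#'
#' `-ln(A/B)` with B the number of template pairs (i < j) within Chebyshev
#' tolerance r at length m and A the corresponding count at length m + 1;
#' self-matches excluded, and the length-m templates restricted to the first
#' N - m so both counts range over the same indices (Richman & Moorman
#' convention). This direct implementation is quadratic in series length and
#' serves as the reference for the KD-tree accelerated version.
#'
#' @inheritParams apen
#' @return dimensionless; `Inf` (with a warning) when A or B is zero.
#' @export
sampen_naive <- function(x, p = entropy_params()) {
  x <- as_intervals(x)
  n <- length(x)
  if (n < p$m + 2) stop("insufficient data", call. = FALSE)
  r <- tolerance_r(x, p)
  Xm1 <- embed_templates(x, p$m + 1)
  nt <- nrow(Xm1)
  Xm <- embed_templates(x, p$m)[seq_len(nt), , drop = FALSE]
  count_pairs <- function(X) {
    cnt <- 0
    for (i in seq_len(nrow(X) - 1)) {
      d <- abs(X[(i + 1):nrow(X), , drop = FALSE] -
                 matrix(X[i, ], nrow(X) - i, ncol(X), byrow = TRUE))
      cnt <- cnt + sum(apply(d, 1, max) <= r)
    }
    cnt
  }
  B <- count_pairs(Xm)
  A <- count_pairs(Xm1)
  if (A == 0 || B == 0) {
    warning("no template matches; SampEn reported as Inf", call. = FALSE)
    return(Inf)
  }
  -log(A / B)
}

#' Sample entropy, KD-tree accelerated
#'
#' Identical value to [sampen_naive()] on every input; the KD-tree changes
#' the cost of counting, not the counts. Templates are delay-embedded, a
#' KD-tree with per-node bounding boxes is built over them, and the m- and
#' (m+1)-length match counts are obtained by Chebyshev-ball range-count
#' queries (whole subtrees accepted or rejected via their boxes), making
#' 20,000-beat series practical.
#'
#' @inheritParams apen
#' @return dimensionless; `Inf` (with a warning) when no matches exist.
#' @export
sampen_kdtree <- function(x, p = entropy_params()) {
  x <- as_intervals(x)
  n <- length(x)
  if (n < p$m + 2) stop("insufficient data", call. = FALSE)
  r <- tolerance_r(x, p)
  Xm1 <- embed_templates(x, p$m + 1)
  nt <- nrow(Xm1)
  Xm <- embed_templates(x, p$m)[seq_len(nt), , drop = FALSE]
  sampen_from_counts(.cheb_range_counts(Xm, r), .cheb_range_counts(Xm1, r))
}

#' Wavelet entropy functional parameters
#'
#' @param threshold_p threshold of the threshold functional (default 0.2).
#' @param sure_p threshold of the sure functional (default 3).
#' @param norm_p exponent of the norm functional, in `[1, 2)` (default 1.1).
#' @param mode `"direct"` applies the functional to the raw samples (the
#'   default; see Details of [wentropy()]); `"wavelet_packet"` first
#'   decomposes the series into terminal wavelet-packet coefficients.
#' @param wavelet wavelet name for packet mode (`"db4"`, `"db2"`, `"haar"`).
#' @param level decomposition level for packet mode.
#' @param log_base base of the logarithm for the shannon and log-energy
#'   functionals (default `exp(1)`).
#' @return list of class `wentropy_params`.
#' @export
wentropy_params <- function(threshold_p = 0.2, sure_p = 3, norm_p = 1.1,
                            mode = c("direct", "wavelet_packet"),
                            wavelet = "db4", level = 4,
                            log_base = exp(1)) {
  mode <- match.arg(mode)
  if (threshold_p < 0 || sure_p < 0 || norm_p < 1 || norm_p >= 2)
    stop("invalid wavelet entropy parameters", call. = FALSE)
  structure(list(threshold_p = threshold_p, sure_p = sure_p,
                 norm_p = norm_p, mode = mode, wavelet = wavelet,
                 level = as.integer(level), log_base = log_base),
            class = "wentropy_params")
}

# orthonormal decomposition lowpass filters (Daubechies)
wavelet_filter <- function(name) {
  switch(name,
    haar = ,
    db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469, 0.48296291314469025),
    db4 = c(-0.010597401784997278, 0.032883011666982945,
            0.030841381835986965, -0.18703481171888114,
            -0.027983769416983849, 0.6308807679295904,
            0.7148465705525415, 0.23037781330885523),
    stop("unknown wavelet: ", name, call. = FALSE))
}

# one periodized analysis step: returns approximation and detail halves
dwt_step <- function(x, lo) {
  n <- length(x)
  if (n %% 2 == 1) { x <- c(x, x[1]); n <- n + 1 }
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  nk <- n / 2
  a <- numeric(nk); d <- numeric(nk)
  for (j in seq_len(L)) {
    idx <- ((2 * seq_len(nk) - 2 + (j - 1)) %% n) + 1
    a <- a + lo[j] * x[idx]
    d <- d + hi[j] * x[idx]
  }
  list(a = a, d = d)
}

# full wavelet-packet decomposition; concatenated terminal-node coefficients
wavelet_packet_coeffs <- function(x, wavelet = "db4", level = 4) {
  lo <- wavelet_filter(wavelet)
  nodes <- list(x)
  for (l in seq_len(level)) {
    nxt <- vector("list", 2 * length(nodes))
    for (i in seq_along(nodes)) {
      st <- dwt_step(nodes[[i]], lo)
      nxt[[2 * i - 1]] <- st$a
      nxt[[2 * i]] <- st$d
    }
    nodes <- nxt
  }
  unlist(nodes, use.names = FALSE)
}

#' Wavelet entropy functionals
#'
#' Additive entropy-style cost functionals `E(S) = sum_i E(S_i)` over the
#' samples of a signal (or, in `wavelet_packet` mode, over its terminal
#' wavelet-packet coefficients):
#' \describe{
#'   \item{shannon}{`-sum(x_i^2 * log(x_i^2))`, with `0*log(0) = 0`.}
#'   \item{log_energy}{`sum(log(x_i^2))`, zero terms contributing 0.}
#'   \item{threshold}{number of samples with `|x_i|` above `threshold_p`.}
#'   \item{sure}{`n - #\{|x_i| <= sure_p\} + sum(min(x_i^2, sure_p^2))`.}
#'   \item{norm}{`sum(|x_i|^norm_p)`.}
#' }
#' Direct mode is the default: at tachogram scale the functional magnitudes
#' (threshold entropy counting essentially every sample, a negative
#' log-energy, a norm near `N * mean(RR)^p`) arise from applying the cost
#' functions to the raw series, and that is the convention the package pins;
#' packet mode is provided for wavelet-domain use.
#'
#' @param x numeric vector or [rr_series].
#' @param kind one of `"shannon"`, `"log_energy"`, `"threshold"`, `"sure"`,
#'   `"norm"`.
#' @param wp a [wentropy_params()].
#' @return dimensionless scalar.
#' @export
wentropy <- function(x, kind = c("shannon", "log_energy", "threshold",
                                 "sure", "norm"),
                     wp = wentropy_params()) {
  kind <- match.arg(kind)
  x <- as_intervals(x)
  if (length(x) == 0) stop("no samples", call. = FALSE)
  if (wp$mode == "wavelet_packet")
    x <- wavelet_packet_coeffs(x, wp$wavelet, wp$level)
  lb <- log(wp$log_base)
  switch(kind,
    shannon = {
      x2 <- x^2
      nz <- x2 > 0
      -sum(x2[nz] * log(x2[nz]) / lb)
    },
    log_energy = {
      x2 <- x^2
      nz <- x2 > 0
      sum(log(x2[nz]) / lb)
    },
    threshold = sum(abs(x) > wp$threshold_p),
    sure = length(x) - sum(abs(x) <= wp$sure_p) +
      sum(pmin(x^2, wp$sure_p^2)),
    norm = sum(abs(x)^wp$norm_p))
}

#' All entropy-based features of a series
#'
#' Approximate entropy, KD-tree sample entropy, and the five wavelet entropy
#' functionals.
#'
#' @param s an [rr_series].
#' @param p an [entropy_params()].
#' @param wp a [wentropy_params()].
#' @return named numeric vector `ApEn`, `SampEn`, `WEShannon`, `WELogEn`,
#'   `WETh`, `WESure`, `WENorm`.
#' @export
entropy_features <- function(s, p = entropy_params(),
                             wp = wentropy_params()) {
  x <- as_intervals(s)
  c(ApEn = apen(x, p),
    SampEn = sampen_kdtree(x, p),
    WEShannon = wentropy(x, "shannon", wp),
    WELogEn = wentropy(x, "log_energy", wp),
    WETh = wentropy(x, "threshold", wp),
    WESure = wentropy(x, "sure", wp),
    WENorm = wentropy(x, "norm", wp))
}
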