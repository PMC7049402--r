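# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops and textbook formulas only.

oracle_pop_sd <- function(x) {
  m <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + (v - m)^2
  sqrt(acc / length(x))
}

# ApEn by direct template counting, self-matches included
oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    nt <- length(x) - mm + 1
    total <- 0
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) cnt <- cnt + 1
      }
      total <- total + log(cnt / nt)
    }
    total / nt
  }
  phi(m) - phi(m + 1)
}

# SampEn pair counts by explicit enumeration (i < j, self-matches excluded,
# both template lengths over the first N - m start indices)
oracle_sampen_counts <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) B <- B + 1
      if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1
    }
  }
  c(A = A, B = B)
}

oracle_sampen <- function(x, m, r) {
  ab <- oracle_sampen_counts(x, m, r)
  -log(ab[["A"]] / ab[["B"]])
}

# Lomb-Scargle power at one frequency, textbook tau-corrected formula with
# explicit trig sums
oracle_lomb_one <- function(t, y, f) {
  w <- 2 * pi * f
  tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
  ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
  0.5 * (sum(y * ct)^2 / sum(ct^2) + sum(y * st)^2 / sum(st^2))
}

# SDANN by explicit window walking
oracle_sdann <- function(intervals, window_s) {
  t0 <- 0
  means <- c()
  cur <- c()
  boundary <- window_s
  for (rr in intervals) {
    if (t0 >= boundary) {
      means <- c(means, mean(cur))
      cur <- c()
      boundary <- boundary + window_s
    }
    cur <- c(cur, rr)
    t0 <- t0 + rr
  }
  if (t0 >= boundary) means <- c(means, mean(cur))  # last window complete
  oracle_pop_sd(means)
}

make_small_cohort <- function(n_per_class = 4, n_samples = 1500, seed = 11) {
  generate_cohort(n_nsr = n_per_class, n_chf = n_per_class,
                  n_samples = n_samples, seed = seed)$cohort
}

# a quick two-cluster feature table for classifier tests
make_cluster_table <- function(n_per_class = 60, d = 4, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  tab <- data.frame(subject_id = sprintf("s%03d", seq_len(2 * n_per_class)),
                    label = factor(rep(c("NSR", "CHF"), each = n_per_class),
                                   levels = c("NSR", "CHF")),
                    X, stringsAsFactors = FALSE)
  names(tab)[-(1:2)] <- paste0("f", seq_len(d))
  tab
}
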