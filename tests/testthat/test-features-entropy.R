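test_that("ApEn is zero for a constant series and ranks noise above a cycle", {
  expect_equal(apen(rep(0.8, 50)), 0)
  set.seed(7)
  periodic <- rep(c(0, 1), 100)
  random <- runif(200)
  expect_lt(apen(periodic), apen(random))
})

test_that("ApEn equals its direct-count oracle", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    m <- sample(1:3, 1)
    x <- cumsum(rnorm(n))
    p <- entropy_params(m = m)
    r <- max(0.15 * hrvmodal:::moment_sd(x), 1e-12)
    expect_equal(apen(x, p), oracle_apen(x, m, r), tolerance = 1e-12)
  }
})

test_that("SampEn matches brute-force pair enumeration and conventions", {
  # hand-enumerable alternating series
  x <- c(1, 2, 1, 2, 1, 2, 1, 2)
  p <- entropy_params(m = 1, r_coeff = 1)      # r = 0.5 = SD(x)
  ab <- oracle_sampen_counts(x, 1, 0.5)
  expect_equal(ab[["B"]], 9)   # pairs among values (1,2,1,2,1,2,1)
  expect_equal(ab[["A"]], 9)   # pairs among the 7 length-2 templates
  expect_equal(sampen_naive(x, p), 0)
  expect_equal(sampen_kdtree(x, p), 0)

  expect_equal(sampen_naive(rep(0.8, 30)), 0)
  expect_equal(sampen_kdtree(rep(0.8, 30)), 0)

  # strictly monotone ramp with r below the step: no matches at all
  ramp <- seq(1, 5, by = 0.2)
  pr <- entropy_params(m = 2, r_coeff = 0.01)
  expect_warning(v <- sampen_naive(ramp, pr), "Inf")
  expect_true(is.infinite(v))
  expect_warning(vk <- sampen_kdtree(ramp, pr), "Inf")
  expect_true(is.infinite(vk))
})

test_that("KD-tree SampEn equals the naive count on random instances", {
  set.seed(11)
  x <- cumsum(rnorm(500))
  expect_equal(sampen_kdtree(x), sampen_naive(x), tolerance = 1e-12)
  for (i in 1:25) {
    n <- sample(50:300, 1)
    m <- sample(1:3, 1)
    x <- cumsum(rnorm(n))
    p <- entropy_params(m = m)
    expect_equal(sampen_kdtree(x, p), sampen_naive(x, p),
                 tolerance = 1e-12)
  }
})

test_that("white noise scores higher than a pure sine at matched length", {
  # 1000 samples: ApEn's small-sample downward bias (sparse template matches
  # at m = 3, r = 0.15 SD) vanishes well below this length
  for (seed in 1:20) {
    set.seed(seed)
    n <- 1000
    noise <- rnorm(n)
    sine <- sin(2 * pi * (1:n) / 25)
    expect_gt(sampen_kdtree(noise), sampen_kdtree(sine))
    expect_gt(apen(noise), apen(sine))
  }
})

test_that("wavelet entropy functionals reproduce closed-form values", {
  expect_equal(wentropy(c(1, 0, 0), "shannon"), 0)
  expect_equal(wentropy(c(0.3, 0.1, 0.5), "threshold"), 2)
  expect_equal(wentropy(c(1, 1), "sure"), 2)
  expect_equal(wentropy(c(1, 1, 1), "norm"), 3)
  expect_equal(wentropy(2, "norm"), 2^1.1, tolerance = 1e-12)
  expect_equal(wentropy(2, "norm"), 2.14355, tolerance = 1e-4)
  expect_equal(wentropy(rep(0.5, 4), "log_energy"), 4 * log(0.25))
  # RR-scale series: every sample exceeds the 0.2 threshold
  s <- generate_subject(default_specs()$NSR, 2000, subject_seed = 2)
  expect_equal(wentropy(s, "threshold"), 2000)
})

test_that("functional structure: homogeneity, monotonicity, permutation invariance", {
  set.seed(5)
  x <- rnorm(100)
  for (a in c(0.5, 3)) {
    expect_equal(wentropy(a * x, "norm"),
                 a^1.1 * wentropy(x, "norm"), tolerance = 1e-10)
  }
  th <- vapply(c(0.1, 0.5, 1, 2),
               function(p) wentropy(x, "threshold",
                                    wentropy_params(threshold_p = p)),
               numeric(1))
  expect_true(all(diff(th) <= 0))
  expect_true(all(th == floor(th)))
  xp <- sample(x)
  expect_equal(wentropy(xp, "shannon"), wentropy(x, "shannon"),
               tolerance = 1e-10)
  expect_equal(wentropy(xp, "log_energy"), wentropy(x, "log_energy"),
               tolerance = 1e-10)
})

test_that("wavelet-packet mode is orthonormal and matches Haar by hand", {
  # one Haar level of [1,2,3,4]: approx (3, 7)/sqrt(2), detail (-1, -1)/sqrt(2)
  co <- hrvmodal:::wavelet_packet_coeffs(c(1, 2, 3, 4), "haar", 1)
  expect_equal(sort(co), sort(c(3, 7, -1, -1) / sqrt(2)))
  set.seed(12)
  x <- rnorm(64)
  for (wv in c("haar", "db2", "db4")) {
    co <- hrvmodal:::wavelet_packet_coeffs(x, wv, 3)
    expect_length(co, 64)
    expect_equal(sum(co^2), sum(x^2), tolerance = 1e-10)
  }
  wp <- wentropy_params(mode = "wavelet_packet", wavelet = "db4", level = 3)
  expect_type(wentropy(x, "shannon", wp), "double")
})

test_that("entropy feature assembly populates all seven fields", {
  s <- generate_subject(default_specs()$NSR, 400, subject_seed = 4)
  f <- entropy_features(s)
  expect_named(f, c("ApEn", "SampEn", "WEShannon", "WELogEn", "WETh",
                    "WESure", "WENorm"))
  expect_true(all(is.finite(f)))

  const <- rr_series(rep(0.8, 60))
  fc <- entropy_features(const)
  expect_equal(fc[["ApEn"]], 0)
  expect_equal(fc[["SampEn"]], 0)
  expect_equal(fc[["WELogEn"]], 60 * log(0.64))
})
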