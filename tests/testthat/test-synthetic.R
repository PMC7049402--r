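test_that("generator is deterministic and produces positive intervals", {
  sp <- default_specs()$NSR
  a <- generate_subject(sp, 500, subject_seed = 9)
  b <- generate_subject(sp, 500, subject_seed = 9)
  expect_identical(a$intervals, b$intervals)
  expect_true(all(a$intervals > 0))

  g1 <- generate_cohort(n_nsr = 3, n_chf = 2, n_samples = 300, seed = 5)
  g2 <- generate_cohort(n_nsr = 3, n_chf = 2, n_samples = 300, seed = 5)
  expect_identical(g1, g2)
  expect_true(all(vapply(g1$cohort,
                         function(s) all(s$intervals > 0), logical(1))))
  g3 <- generate_cohort(n_nsr = 3, n_chf = 2, n_samples = 300, seed = 6)
  expect_false(identical(g1$cohort[[1]]$intervals,
                         g3$cohort[[1]]$intervals))
})

test_that("all modulation off yields a constant series at mean_rr", {
  sp <- class_spec("NSR", mean_rr = 0.8, slow_amp = 0, lf_amp = 0,
                   lf_freq = 0.1, hf_amp = 0, hf_freq = 0.25,
                   noise_sd = 0, irregularity = 0)
  s <- generate_subject(sp, 100, subject_seed = 1)
  expect_equal(s$intervals, rep(0.8, 100))
})

test_that("degenerate specs are rejected", {
  expect_error(class_spec("CHF", mean_rr = 0.2, slow_amp = 0.1,
                          lf_amp = 0.05, lf_freq = 0.1, hf_amp = 0.05,
                          hf_freq = 0.25, noise_sd = 0.05,
                          irregularity = 0),
               "degenerate spec")
  expect_error(class_spec("NSR", 0.8, 0, 0, 0.1, 0, 0.25, 0, 1.5),
               "invalid")
})

test_that("an LF-only spec concentrates spectral power in the LF band", {
  sp <- class_spec("NSR", mean_rr = 0.8, slow_amp = 0, lf_amp = 0.05,
                   lf_freq = 0.10, hf_amp = 0, hf_freq = 0.25,
                   noise_sd = 5e-4, irregularity = 0)
  s <- generate_subject(sp, 2000, subject_seed = 3)
  bp <- band_powers(s)
  expect_gte(bp[["LF"]] / bp[["TP"]], 0.8)
})

test_that("default specs separate the classes in the assumed directions", {
  g <- generate_cohort(n_nsr = 12, n_chf = 12, n_samples = 4000, seed = 0)
  tab <- suppressMessages(assemble_table(g$cohort, "combined"))
  mn <- function(f, lab) mean(tab[[f]][tab$label == lab])
  expect_gt(mn("SDNN", "NSR"), mn("SDNN", "CHF"))
  expect_gt(mn("SampEn", "NSR"), mn("SampEn", "CHF"))
  expect_gt(mn("WENorm", "NSR"), mn("WENorm", "CHF"))
  expect_gt(mn("LFHF", "CHF"), mn("LFHF", "NSR"))
  expect_gt(mn("SDNN", "NSR"), 0.05)
  expect_lt(mn("SDNN", "NSR"), 0.12)
  expect_gt(mn("RMS", "NSR"), 0.7 - 0.098)   # heart rate ~67-86 bpm scale
  expect_lt(mn("RMS", "NSR"), 0.9)
})

test_that("identical class specs carry no class signal (chance-level AUC)", {
  specs <- default_specs()
  specs$CHF <- class_spec("CHF", specs$NSR$mean_rr, specs$NSR$slow_amp,
                          specs$NSR$lf_amp, specs$NSR$lf_freq,
                          specs$NSR$hf_amp, specs$NSR$hf_freq,
                          specs$NSR$noise_sd, specs$NSR$irregularity)
  g <- generate_cohort(n_nsr = 20, n_chf = 20, n_samples = 1200, seed = 2,
                       specs = specs)
  tab <- suppressMessages(assemble_table(g$cohort, "statistical"))
  s <- summary(crossvalidate(tab, "svm_linear", k = 5, seed = 2))
  expect_gt(s$auc, 0.2)
  expect_lt(s$auc, 0.8)
})
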