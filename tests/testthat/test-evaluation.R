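test_that("confusion counts partition the subjects", {
  cm <- confusion(c("P", "P", "N", "N"), c("P", "N", "P", "N"),
                  positive = "P")
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 1, fn = 1, fp = 1, tn = 1))
  perfect <- confusion(c("P", "P", "N"), c("P", "P", "N"), positive = "P")
  expect_equal(perfect$fp + perfect$fn, 0)
  allpos <- confusion(c("P", "N"), c("P", "P"), positive = "P")
  expect_equal(allpos$tn + allpos$fn, 0)
  expect_error(confusion(c("P", "N"), "P"), "equal length")
  expect_error(confusion(c("P", "P"), c("P", "P")), "both classes")
})

test_that("metrics reproduce the printed worked-example values", {
  m <- cm_metrics(confusion_counts(tp = 39, fp = 5, fn = 3, tn = 69,
                                   positive = "CHF"))
  expect_equal(round(100 * m[["TA"]], 1), 93.1)
  expect_equal(m[["TA"]], 108 / 116)

  m2 <- cm_metrics(confusion_counts(tp = 69, fp = 5, fn = 3, tn = 39,
                                    positive = "NSR"))
  expect_equal(round(100 * m2[["TPR"]]), 96)
  expect_equal(round(100 * m2[["TNR"]]), 89)
  expect_equal(round(100 * m2[["PPV"]]), 93)

  m3 <- cm_metrics(confusion_counts(tp = 34, fp = 10, fn = 4, tn = 68,
                                    positive = "CHF"))
  expect_equal(round(100 * m3[["TA"]], 1), 87.9)

  all_right <- cm_metrics(confusion_counts(10, 0, 0, 12))
  expect_equal(unname(all_right), rep(1, 5))
})

test_that("relabelling the positive class swaps the paired metrics", {
  truth <- rep(c("NSR", "CHF"), c(12, 9))
  set.seed(2)
  pred <- sample(truth)
  a <- cm_metrics(confusion(truth, pred, positive = "NSR"))
  b <- cm_metrics(confusion(truth, pred, positive = "CHF"))
  expect_equal(a[["TPR"]], b[["TNR"]])
  expect_equal(a[["PPV"]], b[["NPV"]])
  expect_equal(a[["TA"]], b[["TA"]])
})

test_that("rank AUC behaves like the Mann-Whitney statistic", {
  lab <- rep(c("P", "N"), each = 4)
  expect_equal(auc(c(5, 6, 7, 8, 1, 2, 3, 4), lab, "P"), 1)
  expect_equal(auc(c(1, 2, 3, 4, 5, 6, 7, 8), lab, "P"), 0)
  expect_equal(auc(rep(1, 8), lab, "P"), 0.5)
  expect_error(auc(1:3, c("P", "P", "P"), "P"), "both classes")

  set.seed(3)
  sc <- rnorm(2000)
  lab <- rep(c("P", "N"), each = 1000)
  expect_equal(auc(sc, lab, "P"), 0.5, tolerance = 0.03)

  # invariance under strictly monotone transforms; complement under reversal
  set.seed(4)
  sc <- rnorm(200) + rep(c(1, 0), each = 100)
  lab <- rep(c("P", "N"), each = 100)
  a <- auc(sc, lab, "P")
  expect_equal(auc(exp(sc), lab, "P"), a, tolerance = 1e-12)
  expect_equal(auc(-sc, lab, "P"), 1 - a, tolerance = 1e-12)
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- rnorm(150) + rep(c(0.8, 0), c(70, 80))
  lab <- rep(c("P", "N"), c(70, 80))
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                        levels = c("N", "P"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(auc(sc, lab, "P"), ref, tolerance = 1e-12)
})

test_that("the 95% CI matches hand evaluation and scales as 1/sqrt(n)", {
  ci <- ci95(c(0.8, 0.9, 1.0))
  expect_equal(unname(ci), c(0.78684, 1.01316), tolerance = 1e-4)
  expect_equal(mean(ci), 0.9)

  cc <- ci95(rep(0.7, 5))
  expect_equal(unname(cc), c(0.7, 0.7))

  v <- c(0.8, 0.9, 1.0, 1.1)
  w1 <- diff(ci95(v))
  w4 <- diff(ci95(rep(v, 4)))
  # replicating 4x quarters n; the sample-SD finite correction gives
  # sqrt(4*(n-1)/(4n-1))/2 rather than exactly 1/2
  expect_equal(unname(w4 / w1), sqrt(4 * 3 / 15) / 2, tolerance = 1e-9)
  expect_error(ci95(0.5), "at least two")
})

test_that("feature significance separates what should separate", {
  set.seed(6)
  n <- 50
  tab <- data.frame(
    subject_id = sprintf("s%d", 1:(2 * n)),
    label = factor(rep(c("NSR", "CHF"), each = n),
                   levels = c("NSR", "CHF")),
    strong = c(rnorm(n, 10), rnorm(n, 0)),   # 10 SD apart
    null = rnorm(2 * n),
    stringsAsFactors = FALSE)
  sig <- feature_significance(tab)
  expect_equal(nrow(sig), 2)
  expect_lt(sig$p_value[sig$feature == "strong"], 1e-10)
  expect_gt(sig$p_value[sig$feature == "null"], 0.01)
  expect_equal(sig$signif[sig$feature == "null"], "")

  tab$null <- rep(1, 2 * n)
  expect_warning(sig2 <- feature_significance(tab), "no variance")
  expect_equal(sig2$p_value[sig2$feature == "null"], 1)
})
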