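test_that("feature tables carry exactly the requested family", {
  coh <- make_small_cohort(3, 1500, seed = 4)
  expect_equal(ncol(suppressMessages(assemble_table(coh, "time"))) - 2, 4)
  expect_equal(ncol(suppressMessages(assemble_table(coh, "frequency"))) - 2,
               6)
  expect_equal(ncol(suppressMessages(assemble_table(coh, "statistical"))) - 2,
               5)
  expect_equal(ncol(suppressMessages(assemble_table(coh, "entropy"))) - 2, 7)
  tab <- suppressMessages(assemble_table(coh, "combined"))
  expect_equal(ncol(tab) - 2, 22)
  expect_equal(names(tab)[3:6], c("SDANN", "SDNN", "SDSD", "RMSSD"))
  expect_true(all(is.finite(as.matrix(tab[, -(1:2)]))))
  expect_error(assemble_table(list()), "empty cohort")
})

test_that("the preset registry matches the documented battery", {
  reg <- preset_registry()
  expect_length(reg, 14)
  expect_equal(reg$svm_fine_gaussian$hyperparams$kernel_scale, 0.61)
  expect_equal(reg$svm_medium_gaussian$hyperparams$kernel_scale, 2.4)
  expect_equal(reg$svm_coarse_gaussian$hyperparams$kernel_scale, 9.8)
  expect_equal(reg$svm_quadratic$hyperparams$degree, 2)
  expect_equal(reg$svm_cubic$hyperparams$degree, 3)
  expect_equal(reg$knn_fine$hyperparams$K, 3)
  expect_equal(reg$knn_cosine$hyperparams$distance, "cosine")
  expect_equal(reg$ensemble_bagged_tree$hyperparams$n_learners, 30)
  expect_error(get_preset("svm_septic"), "unknown preset")
})

test_that("well-separated clusters are classified perfectly", {
  tab <- make_cluster_table(n_per_class = 60, sep = 6, seed = 1)
  s <- summary(crossvalidate(tab, "svm_linear", k = 10, seed = 1))
  expect_equal(s$metrics[["TA"]], 1)
  expect_equal(s$auc, 1)
})

test_that("permuted labels score at chance level", {
  tab <- make_cluster_table(n_per_class = 30, sep = 6, seed = 2)
  aucs <- vapply(1:20, function(i) {
    set.seed(i)
    tab$label <- sample(tab$label)
    if (min(table(tab$label)) < 5) return(NA_real_)
    summary(crossvalidate(tab, "knn_fine", k = 5, seed = 2))$auc
  }, numeric(1))
  expect_equal(mean(aucs, na.rm = TRUE), 0.5, tolerance = 0.15)
})

test_that("every preset is deterministic under a fixed seed", {
  tab <- make_cluster_table(n_per_class = 25, sep = 2, seed = 3)
  for (pr in names(preset_registry())) {
    a <- crossvalidate(tab, pr, k = 5, seed = 7)
    b <- crossvalidate(tab, pr, k = 5, seed = 7)
    expect_identical(a$score, b$score, info = pr)
    expect_identical(a$pred, b$pred, info = pr)
  }
})

test_that("folds are stratified within one subject of proportionality", {
  tab <- make_cluster_table(n_per_class = 36, sep = 2, seed = 4)
  tab$label <- factor(rep(c("NSR", "CHF"), c(44, 28)),
                      levels = c("NSR", "CHF"))
  cv <- crossvalidate(tab, "fine_tree", k = 10, seed = 5)
  expect_equal(sort(unique(cv$fold)), 1:10)
  per_fold <- table(cv$fold, cv$label)
  for (cl in c("NSR", "CHF")) {
    cnt <- per_fold[, cl]
    expect_lte(max(cnt) - min(cnt), 1)
  }
  # every subject in exactly one test fold
  expect_length(cv$fold, nrow(tab))
})

test_that("standardisation uses training folds only (no leakage)", {
  tab <- make_cluster_table(n_per_class = 30, sep = 4, seed = 6)
  cv1 <- crossvalidate(tab, "svm_linear", k = 5, seed = 9)
  victim <- 7
  f <- cv1$fold[victim]
  tab2 <- tab
  tab2[victim, -(1:2)] <- 1e6   # extreme held-out subject
  cv2 <- crossvalidate(tab2, "svm_linear", k = 5, seed = 9)
  expect_identical(cv2$fold, cv1$fold)
  # the fold where the subject is held out trains without it: stats unchanged
  expect_equal(cv2$fold_meta[[f]], cv1$fold_meta[[f]], tolerance = 1e-12)
})

test_that("degenerate tables are rejected", {
  tab <- make_cluster_table(10, seed = 8)
  one <- tab[tab$label == "NSR", ]
  expect_error(crossvalidate(one, "svm_linear", k = 2, seed = 1),
               "single class")
  expect_error(crossvalidate(tab, "svm_linear", k = 1, seed = 1), "k must")
  expect_error(crossvalidate(tab, "svm_linear", k = 50, seed = 1),
               "reduce k")
})
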