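FEATURE_SETS <- list(
  time = c("SDANN", "SDNN", "SDSD", "RMSSD"),
  frequency = c("TP", "ULF", "VLF", "LF", "HF", "LFHF"),
  statistical = c("RMS", "Var", "Skewness", "Kurtosis", "Smoothness"),
  entropy = c("ApEn", "SampEn", "WEShannon", "WELogEn", "WETh", "WESure",
              "WENorm"))
FEATURE_SETS$combined <- unlist(FEATURE_SETS[c("time", "frequency",
                                               "statistical", "entropy")],
                                use.names = FALSE)

#' Assemble the subjects-by-features table
#'
#' Computes the chosen feature family for every subject of a cohort and
#' returns a data.frame with `subject_id`, `label` and one column per
#' feature. `combined` concatenates all 22 features (4 time-domain, 6
#' frequency-domain, 5 statistical, 7 entropy-based). Infinite feature
#' values (the LF/HF and SampEn sentinels) are winsorised to the finite
#' column maximum so the table is classifier-ready; each replacement is
#' reported via a message.
#'
#' @param cohort list of [rr_series].
#' @param feature_set one of `"combined"`, `"time"`, `"frequency"`,
#'   `"statistical"`, `"entropy"`.
#' @param scheme a [band_scheme()] for the spectral features.
#' @param p an [entropy_params()].
#' @param wp a [wentropy_params()].
#' @param method PSD estimator for [band_powers()].
#' @param window_s SDANN window, seconds.
#' @return data.frame of class `hrv_features`.
#' @export
assemble_table <- function(cohort, feature_set = "combined",
                           scheme = band_scheme(), p = entropy_params(),
                           wp = wentropy_params(), method = "lomb",
                           window_s = 300) {
  feature_set <- match.arg(feature_set, names(FEATURE_SETS))
  if (length(cohort) == 0) stop("empty cohort", call. = FALSE)
  want <- FEATURE_SETS[[feature_set]]
  rows <- lapply(cohort, function(s) {
    tryCatch({
      f <- c(
        if (feature_set %in% c("time", "combined"))
          time_features(s, window_s = window_s),
        if (feature_set %in% c("frequency", "combined"))
          band_powers(s, scheme, method),
        if (feature_set %in% c("statistical", "combined"))
          stat_features(s),
        if (feature_set %in% c("entropy", "combined"))
          entropy_features(s, p, wp))
      f[want]
    }, error = function(e)
      stop(sprintf("subject '%s': %s", s$subject_id,
                   conditionMessage(e)), call. = FALSE))
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- want
  # winsorise infinite sentinels to the finite column max
  for (j in seq_len(ncol(mat))) {
    inf <- is.infinite(mat[, j])
    if (any(inf)) {
      fin <- mat[!inf, j]
      repl <- if (length(fin)) max(fin) else 0
      message(sprintf("winsorised %d infinite value(s) in %s to %g",
                      sum(inf), colnames(mat)[j], repl))
      mat[inf, j] <- repl
    }
  }
  out <- data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    label = factor(vapply(cohort, `[[`, "", "label"),
                   levels = c("NSR", "CHF")),
    mat, stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "feature_set") <- feature_set
  class(out) <- c("hrv_features", "data.frame")
  out
}

#' Classifier preset registry
#'
#' Declarative descriptions of the classifier battery: fine and coarse
#' decision trees; linear, quadratic, cubic and fine/medium/coarse Gaussian
#' SVMs (kernel scales 0.61, 2.4 and 9.8, applied to standardised features
#' as `gamma = 1/(2*scale^2)`); fine, medium and cosine KNN (K = 3,
#' Euclidean distance for fine/medium, cosine for the third); and bagged
#' tree, random-subspace discriminant and RUSBoosted tree ensembles of 30
#' learners each. The presets are bound to established solvers (libsvm via
#' e1071, rpart, randomForest, MASS::lda) at fit time.
#'
#' @return named list of classifier specs (`family`, `preset`,
#'   `hyperparams`).
#' @export
preset_registry <- function() {
  spec <- function(family, preset, ...)
    list(family = family, preset = preset, hyperparams = list(...))
  list(
    fine_tree = spec("tree", "fine_tree", max_depth = 30, cp = 0,
                     min_split = 5),
    coarse_tree = spec("tree", "coarse_tree", max_depth = 2, cp = 0,
                       min_split = 5),
    svm_linear = spec("svm", "svm_linear", kernel = "linear"),
    svm_quadratic = spec("svm", "svm_quadratic", kernel = "polynomial",
                         degree = 2),
    svm_cubic = spec("svm", "svm_cubic", kernel = "polynomial", degree = 3),
    svm_fine_gaussian = spec("svm", "svm_fine_gaussian", kernel = "radial",
                             kernel_scale = 0.61),
    svm_medium_gaussian = spec("svm", "svm_medium_gaussian",
                               kernel = "radial", kernel_scale = 2.4),
    svm_coarse_gaussian = spec("svm", "svm_coarse_gaussian",
                               kernel = "radial", kernel_scale = 9.8),
    knn_fine = spec("knn", "knn_fine", K = 3, distance = "euclidean"),
    knn_medium = spec("knn", "knn_medium", K = 3, distance = "euclidean"),
    knn_cosine = spec("knn", "knn_cosine", K = 3, distance = "cosine"),
    ensemble_bagged_tree = spec("ensemble", "ensemble_bagged_tree",
                                type = "bag", n_learners = 30),
    ensemble_subspace_discriminant = spec("ensemble",
                                          "ensemble_subspace_discriminant",
                                          type = "subspace", n_learners = 30),
    ensemble_rusboosted_tree = spec("ensemble", "ensemble_rusboosted_tree",
                                    type = "rusboost", n_learners = 30,
                                    max_depth = 3))
}

#' Look up one classifier preset
#'
#' @param name preset name (see [preset_registry()]).
#' @return a classifier spec.
#' @export
get_preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset: ", name, call. = FALSE)
  reg[[name]]
}

# training-fold z-scoring; zero-SD columns pass through unscaled
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(center = mu, scale = sdv)
}
standardize_apply <- function(X, st)
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")

stratified_folds <- function(labels, k, seed) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (min(table(labels)) < k)
    stop("each fold must contain at least one subject of each class; ",
         "reduce k", call. = FALSE)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# ---- per-family fit/predict; all return NSR-oriented scores in [higher =>
# more NSR-like] plus predicted labels -------------------------------------

fit_predict <- function(spec, Xtr, ytr, Xte, fold_seed) {
  hp <- spec$hyperparams
  switch(spec$family,
    tree = {
      fit <- rpart::rpart(y ~ ., data = data.frame(Xtr, y = ytr),
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = hp$max_depth, cp = hp$cp,
                            minsplit = hp$min_split, xval = 0))
      pr <- predict(fit, data.frame(Xte), type = "prob")
      pr[, "NSR"]
    },
    svm = {
      args <- list(x = Xtr, y = ytr, kernel = hp$kernel, scale = FALSE,
                   cost = 1, probability = FALSE)
      if (!is.null(hp$degree)) {
        args$degree <- hp$degree
        args$gamma <- 1
        args$coef0 <- 1
      }
      if (!is.null(hp$kernel_scale))
        args$gamma <- 1 / (2 * hp$kernel_scale^2)
      fit <- do.call(e1071::svm, args)
      pr <- predict(fit, Xte, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      pos <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
      if (pos == "NSR") dv else -dv
    },
    knn = knn_score(Xtr, ytr, Xte, hp$K, hp$distance),
    ensemble = switch(hp$type,
      bag = {
        with_seed(fold_seed,
          fit <- randomForest::randomForest(
            x = Xtr, y = ytr, ntree = hp$n_learners, mtry = ncol(Xtr),
            replace = TRUE))
        predict(fit, Xte, type = "prob")[, "NSR"]
      },
      subspace = subspace_discriminant_score(Xtr, ytr, Xte,
                                             hp$n_learners, fold_seed),
      rusboost = rusboost_score(Xtr, ytr, Xte, hp$n_learners,
                                hp$max_depth, fold_seed)))
}

knn_score <- function(Xtr, ytr, Xte, K, distance) {
  if (distance == "cosine") {
    nrm <- function(M) {
      nn <- sqrt(rowSums(M^2))
      nn[nn == 0] <- 1
      M / nn
    }
    Xtr <- nrm(Xtr); Xte <- nrm(Xte)
  }
  vapply(seq_len(nrow(Xte)), function(i) {
    d <- sqrt(rowSums(sweep(Xtr, 2, Xte[i, ])^2))
    nb <- order(d)[seq_len(K)]          # order() breaks ties by index
    mean(ytr[nb] == "NSR")
  }, numeric(1))
}

subspace_discriminant_score <- function(Xtr, ytr, Xte, n_learners,
                                        fold_seed) {
  d <- ncol(Xtr)
  sdim <- ceiling(d / 2)
  with_seed(fold_seed, {
    acc <- numeric(nrow(Xte)); used <- 0
    for (b in seq_len(n_learners)) {
      cols <- sort(sample.int(d, sdim))
      fit <- tryCatch(
        suppressWarnings(MASS::lda(Xtr[, cols, drop = FALSE], ytr)),
        error = function(e) NULL)
      if (is.null(fit)) next
      post <- predict(fit, Xte[, cols, drop = FALSE])$posterior
      acc <- acc + post[, "NSR"]
      used <- used + 1
    }
    if (used == 0) rep(0.5, nrow(Xte)) else acc / used
  })
}

# AdaBoost.M1 with per-iteration random undersampling of the majority class
rusboost_score <- function(Xtr, ytr, Xte, n_learners, max_depth,
                           fold_seed) {
  n <- nrow(Xtr)
  w <- rep(1 / n, n)
  minority <- names(which.min(table(ytr)))
  min_idx <- which(ytr == minority)
  maj_idx <- which(ytr != minority)
  with_seed(fold_seed, {
    F_nsr <- numeric(nrow(Xte)); alpha_sum <- 0
    for (b in seq_len(n_learners)) {
      take <- sample(maj_idx, length(min_idx), replace = FALSE,
                     prob = w[maj_idx] / sum(w[maj_idx]))
      idx <- c(min_idx, take)
      fit <- rpart::rpart(y ~ ., data = data.frame(Xtr, y = ytr)[idx, ],
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = max_depth, cp = 0, minsplit = 5,
                            xval = 0))
      pred <- predict(fit, data.frame(Xtr), type = "class")
      err <- sum(w * (pred != ytr))
      err <- min(max(err, 1e-10), 1 - 1e-10)
      alpha <- 0.5 * log((1 - err) / err)
      if (alpha <= 0) next
      w <- w * exp(alpha * ifelse(pred != ytr, 1, -1))
      w <- w / sum(w)
      F_nsr <- F_nsr + alpha *
        predict(fit, data.frame(Xte), type = "prob")[, "NSR"]
      alpha_sum <- alpha_sum + alpha
    }
    if (alpha_sum == 0) rep(0.5, nrow(Xte)) else F_nsr / alpha_sum
  })
}

#' Cross-validated classifier evaluation
#'
#' The package's central fitting function. Runs stratified k-fold
#' cross-validation of one classifier preset on a feature table: folds are
#' stratified by class (per-fold class counts within one subject of
#' proportionality), features are z-scored using training-fold statistics
#' only, and each held-out fold receives a predicted label and a continuous
#' score oriented so that larger means more NSR-like. All randomness (fold
#' assignment, ensemble resampling) derives from `seed`, so the result is
#' fully reproducible.
#'
#' @param table an [assemble_table()] result (or any data.frame with
#'   `subject_id`, `label` and numeric feature columns).
#' @param preset preset name or a spec from [preset_registry()].
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param positive_class the class treated as "positive" by downstream
#'   reports (default `"NSR"`).
#' @return object of class `hrv_cv` with fields `subject_id`, `label`,
#'   `fold`, `pred`, `score` (NSR-oriented), `fold_meta` (per-fold
#'   standardisation statistics), plus the call parameters. Use
#'   [summary.hrv_cv()] for the performance report.
#' @seealso [summary.hrv_cv()], [plot.hrv_cv()]
#' @export
crossvalidate <- function(table, preset = "svm_linear", k = 10, seed = 0,
                          positive_class = "NSR") {
  if (is.character(preset)) preset <- get_preset(preset)
  labels <- factor(as.character(table$label), levels = c("NSR", "CHF"))
  if (any(is.na(labels))) stop("labels must be NSR or CHF", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2)
    stop("feature table contains a single class", call. = FALSE)
  feat_cols <- setdiff(names(table), c("subject_id", "label"))
  X <- as.matrix(as.data.frame(table)[, feat_cols, drop = FALSE])
  if (!all(is.finite(X))) stop("non-finite feature values", call. = FALSE)
  fold <- stratified_folds(labels, k, seed)
  score <- numeric(nrow(X))
  fold_meta <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    st <- standardize_fit(X[tr, , drop = FALSE])
    fold_meta[[f]] <- st
    Xtr <- standardize_apply(X[tr, , drop = FALSE], st)
    Xte <- standardize_apply(X[te, , drop = FALSE], st)
    fold_seed <- (seed * 1009 + f * 7919) %% 2147483629
    score[te] <- fit_predict(preset, Xtr, labels[tr], Xte, fold_seed)
  }
  pred <- factor(ifelse(score > median_threshold(preset), "NSR", "CHF"),
                 levels = c("NSR", "CHF"))
  structure(
    list(subject_id = table$subject_id, label = labels, fold = fold,
         pred = pred, score = score, fold_meta = fold_meta,
         preset = preset$preset, feature_set =
           attr(table, "feature_set") %||% "custom",
         k = k, seed = seed, positive_class = positive_class),
    class = "hrv_cv")
}

# decision threshold on the NSR-oriented score: probability-like scores cut
# at 1/2, margin-like (SVM decision value) at 0
median_threshold <- function(spec) {
  if (spec$family == "svm") 0 else 0.5
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hrv_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of '%s' on %s features\n",
              x$k, x$preset, x$feature_set))
  cat(sprintf("  %d subjects (%s), seed %d, positive class %s\n",
              length(x$label),
              paste(sprintf("%d %s", table(x$label), names(table(x$label))),
                    collapse = " + "),
              x$seed, x$positive_class))
  s <- summary(x)
  cat(sprintf("  TA %.1f%%, AUC %.2f\n", 100 * s$metrics[["TA"]], s$auc))
  invisible(x)
}

#' Out-of-fold predictions of a cross-validated classifier
#'
#' @param object an `hrv_cv` object.
#' @param ... unused.
#' @return data.frame with `subject_id`, `label`, `fold`, `pred`, `score`.
#' @export
predict.hrv_cv <- function(object, ...) {
  data.frame(subject_id = object$subject_id,
             label = object$label, fold = object$fold,
             pred = object$pred, score = object$score,
             stringsAsFactors = FALSE)
}
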