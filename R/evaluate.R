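#' Confusion matrix with an explicit positive class
#'
#' @param truth,pred equal-length label vectors.
#' @param positive the class counted as positive.
#' @return object of class `hrv_confusion`: list `tp`, `fp`, `fn`, `tn`,
#'   `positive_class`.
#' @export
confusion <- function(truth, pred, positive = "NSR") {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  if (length(unique(truth)) < 2)
    stop("both classes must be present in truth", call. = FALSE)
  confusion_counts(tp = sum(truth == positive & pred == positive),
                   fp = sum(truth != positive & pred == positive),
                   fn = sum(truth == positive & pred != positive),
                   tn = sum(truth != positive & pred != positive),
                   positive = positive)
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @param positive positive-class tag.
#' @return object of class `hrv_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn, positive = "NSR") {
  if (any(c(tp, fp, fn, tn) < 0) || tp + fp + fn + tn < 1)
    stop("invalid confusion counts", call. = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 positive_class = positive),
            class = "hrv_confusion")
}

#' @export
print.hrv_confusion <- function(x, ...) {
  cat(sprintf("confusion (positive = %s): TP %d, FP %d, FN %d, TN %d\n",
              x$positive_class, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' TPR (sensitivity) = TP/(TP+FN), TNR (specificity) = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN), TA = (TP+TN)/total. Values are
#' proportions in `[0, 1]`; rendering as percentages is a display concern
#' (TA to one decimal, the rates to the nearest percent). A zero denominator
#' yields `NA` with a warning.
#'
#' @param cm an [confusion()] / [confusion_counts()] object.
#' @return named numeric vector `TPR`, `TNR`, `PPV`, `NPV`, `TA`.
#' @export
cm_metrics <- function(cm) {
  stopifnot(inherits(cm, "hrv_confusion"))
  rate <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  c(TPR = rate(cm$tp, cm$tp + cm$fn, "TPR"),
    TNR = rate(cm$tn, cm$tn + cm$fp, "TNR"),
    PPV = rate(cm$tp, cm$tp + cm$fp, "PPV"),
    NPV = rate(cm$tn, cm$tn + cm$fn, "NPV"),
    TA = (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$fn + cm$tn))
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks; equal
#' to the trapezoidal area under the empirical ROC curve and invariant under
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric scores, larger meaning more positive-class-like.
#' @param labels class labels.
#' @param positive the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = "NSR") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normal-theory 95% confidence interval for a mean
#'
#' `mean(values) +/- 1.95996 * sd(values)/sqrt(n)` with the sample standard
#' deviation — the textbook large-sample interval, applied in this package
#' to the per-fold accuracy estimates of a cross-validation run.
#'
#' @param values numeric vector, `n >= 2`.
#' @return named vector `CI_low`, `CI_high`.
#' @export
ci95 <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least two values", call. = FALSE)
  m <- mean(values)
  me <- 1.95996 * stats::sd(values) / sqrt(n)
  c(CI_low = m - me, CI_high = m + me)
}

#' Per-feature class contrast and Welch test
#'
#' For every feature column: mean and SD per class and the two-sample
#' Welch (unequal-variance) t-test p-value, with significance tiers
#' `***` (p below 1e-50), `**` (below 1e-25), `*` (below 0.01).
#'
#' @param table an [assemble_table()] result.
#' @return data.frame with one row per feature: `feature`, `chf_mean`,
#'   `chf_sd`, `nsr_mean`, `nsr_sd`, `p_value`, `signif`.
#' @export
feature_significance <- function(table) {
  labels <- factor(as.character(table$label), levels = c("NSR", "CHF"))
  if (min(table(labels)) < 2)
    stop("need at least two subjects per class", call. = FALSE)
  feat_cols <- setdiff(names(table), c("subject_id", "label"))
  rows <- lapply(feat_cols, function(fc) {
    x <- as.data.frame(table)[[fc]]
    a <- x[labels == "CHF"]; b <- x[labels == "NSR"]
    p <- tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
                  error = function(e) {
                    warning("feature '", fc,
                            "' has no variance; p-value set to 1",
                            call. = FALSE)
                    1
                  })
    data.frame(feature = fc,
               chf_mean = mean(a), chf_sd = stats::sd(a),
               nsr_mean = mean(b), nsr_sd = stats::sd(b),
               p_value = p,
               signif = if (p < 1e-50) "***" else if (p < 1e-25) "**"
                        else if (p < 0.01) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Performance report of a cross-validated classifier
#'
#' Builds the confusion matrix of the out-of-fold predictions with the run's
#' positive class, the five ratio metrics, the rank AUC of the out-of-fold
#' scores (oriented toward the positive class), and the 95% confidence
#' interval of the per-fold accuracies.
#'
#' @param object an `hrv_cv` object from [crossvalidate()].
#' @param positive_class override of the object's positive class.
#' @param ... unused.
#' @return object of class `summary.hrv_cv`: list with `confusion`,
#'   `metrics`, `auc`, `ci`, `fold_accuracy` and the run descriptors.
#' @export
summary.hrv_cv <- function(object, positive_class = NULL, ...) {
  pc <- positive_class %||% object$positive_class
  cm <- confusion(object$label, object$pred, positive = pc)
  sc <- if (pc == "NSR") object$score else -object$score
  fold_acc <- vapply(seq_len(object$k), function(f) {
    sel <- object$fold == f
    mean(object$pred[sel] == object$label[sel])
  }, numeric(1))
  structure(
    list(preset = object$preset, feature_set = object$feature_set,
         k = object$k, seed = object$seed, positive_class = pc,
         confusion = cm, metrics = cm_metrics(cm),
         auc = auc(sc, object$label, positive = pc),
         fold_accuracy = fold_acc, ci = ci95(fold_acc)),
    class = "summary.hrv_cv")
}

#' @export
print.summary.hrv_cv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("%s / %s features, %d-fold CV (positive = %s)\n",
              x$preset, x$feature_set, x$k, x$positive_class))
  print(x$confusion)
  cat(sprintf("  TPR %.0f%%  TNR %.0f%%  PPV %.0f%%  NPV %.0f%%  TA %.1f%%\n",
              100 * m[["TPR"]], 100 * m[["TNR"]], 100 * m[["PPV"]],
              100 * m[["NPV"]], 100 * m[["TA"]]))
  cat(sprintf("  AUC %.2f, fold-accuracy 95%% CI [%.3f, %.3f]\n",
              x$auc, x$ci[["CI_low"]], x$ci[["CI_high"]]))
  invisible(x)
}

#' ROC curve of a cross-validated classifier
#'
#' Plots the empirical ROC of the out-of-fold scores (positive class as per
#' the run) with the chance diagonal.
#'
#' @param x an `hrv_cv` object.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, a data.frame of the ROC points (`fpr`, `tpr`).
#' @export
plot.hrv_cv <- function(x, ...) {
  pc <- x$positive_class
  sc <- if (pc == "NSR") x$score else -x$score
  pos <- as.character(x$label) == pc
  ord <- order(sc, decreasing = TRUE)
  tpr <- c(0, cumsum(pos[ord]) / sum(pos))
  fpr <- c(0, cumsum(!pos[ord]) / sum(!pos))
  graphics::plot(fpr, tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("ROC: %s (%s)", x$preset, x$feature_set),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(data.frame(fpr = fpr, tpr = tpr))
}

# serialisable report list (the JSON schema of the bundle writers)
report_as_list <- function(s, cv) {
  list(preset = s$preset, feature_set = s$feature_set, folds = s$k,
       seed = s$seed,
       confusion = list(tp = s$confusion$tp, fp = s$confusion$fp,
                        fn = s$confusion$fn, tn = s$confusion$tn,
                        positive_class = s$positive_class),
       metrics = list(TPR = s$metrics[["TPR"]], TNR = s$metrics[["TNR"]],
                      PPV = s$metrics[["PPV"]], NPV = s$metrics[["NPV"]],
                      TA = s$metrics[["TA"]], AUC = s$auc,
                      CI_low = s$ci[["CI_low"]],
                      CI_high = s$ci[["CI_high"]]),
       per_subject = lapply(seq_along(cv$subject_id), function(i)
         list(subject_id = cv$subject_id[i],
              label = as.character(cv$label[i]), fold = cv$fold[i],
              pred = as.character(cv$pred[i]), score = cv$score[i])))
}
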