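#' Pipeline run configuration
#'
#' Collects everything a full simulate/load -> extract -> classify ->
#' evaluate run needs. Either `manifest` (path to a cohort manifest CSV) or
#' `simulate = TRUE` (synthetic cohort) must be chosen. Presets are
#' validated against [preset_registry()] up front, before any computation.
#'
#' @param simulate generate a synthetic cohort (default TRUE).
#' @param manifest manifest CSV path when `simulate = FALSE`.
#' @param n_nsr,n_chf,n_samples synthetic cohort dimensions.
#' @param feature_set feature family for [assemble_table()].
#' @param presets character vector of preset names.
#' @param folds,seed cross-validation folds and top-level seed.
#' @param positive_class positive class for reports.
#' @param out_dir optional output directory for the report bundle.
#' @param scheme,entropy,wentropy parameter objects ([band_scheme()],
#'   [entropy_params()], [wentropy_params()]).
#' @param psd_method `"lomb"` or `"resample_welch"`.
#' @return list of class `hrv_run_config`.
#' @export
run_config <- function(simulate = TRUE, manifest = NULL,
                       n_nsr = 72, n_chf = 44, n_samples = 20000,
                       feature_set = "combined",
                       presets = "svm_linear", folds = 10, seed = 0,
                       positive_class = "NSR", out_dir = NULL,
                       scheme = band_scheme(), entropy = entropy_params(),
                       wentropy = wentropy_params(), psd_method = "lomb") {
  reg <- preset_registry()
  bad <- setdiff(presets, names(reg))
  if (length(bad))
    stop("unknown preset(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (!simulate && is.null(manifest))
    stop("either simulate = TRUE or a manifest path is required",
         call. = FALSE)
  feature_set <- match.arg(feature_set, names(FEATURE_SETS))
  structure(list(simulate = simulate, manifest = manifest, n_nsr = n_nsr,
                 n_chf = n_chf, n_samples = n_samples,
                 feature_set = feature_set, presets = presets,
                 folds = folds, seed = seed,
                 positive_class = positive_class, out_dir = out_dir,
                 scheme = scheme, entropy = entropy, wentropy = wentropy,
                 psd_method = psd_method),
            class = "hrv_run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields of [run_config()] may be given in a YAML mapping;
#' unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [run_config()].
#' @return an `hrv_run_config`.
#' @export
run_config_from_yaml <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  over <- list(...)
  cfg[names(over)] <- over
  do.call(run_config, cfg)
}

write_json_file <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

#' Run the full pipeline
#'
#' Simulates or loads the cohort, assembles the feature table, computes the
#' per-feature significance table, cross-validates every configured preset,
#' and (when `out_dir` is set) writes the bundle: `features.csv`,
#' `significance.csv`, one `report_<preset>.json` per preset, and
#' `run_manifest.json` recording the parameters and seed derivation. The
#' bundle is a pure function of the configuration: identical configurations
#' yield byte-identical files.
#'
#' @param cfg an [run_config()].
#' @return list with `table`, `significance`, `cv` (named list of `hrv_cv`),
#'   `reports` (named list of report lists), invisibly the written paths in
#'   attribute `"paths"`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "hrv_run_config"))
  cohort <- if (cfg$simulate)
    generate_cohort(cfg$n_nsr, cfg$n_chf, cfg$n_samples, cfg$seed)$cohort
  else
    load_cohort(cfg$manifest, n = cfg$n_samples)
  table <- assemble_table(cohort, cfg$feature_set, scheme = cfg$scheme,
                          p = cfg$entropy, wp = cfg$wentropy,
                          method = cfg$psd_method)
  sig <- feature_significance(table)
  cvs <- list(); reports <- list()
  for (pr in cfg$presets) {
    cv <- crossvalidate(table, pr, k = cfg$folds, seed = cfg$seed,
                        positive_class = cfg$positive_class)
    cvs[[pr]] <- cv
    reports[[pr]] <- report_as_list(summary(cv), cv)
  }
  paths <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    fpath <- file.path(cfg$out_dir, "features.csv")
    utils::write.csv(as.data.frame(table), fpath, row.names = FALSE)
    spath <- file.path(cfg$out_dir, "significance.csv")
    utils::write.csv(sig, spath, row.names = FALSE)
    rpaths <- vapply(names(reports), function(pr) {
      p <- file.path(cfg$out_dir, paste0("report_", pr, ".json"))
      write_json_file(reports[[pr]], p)
      p
    }, "")
    mpath <- file.path(cfg$out_dir, "run_manifest.json")
    write_json_file(list(
      feature_set = cfg$feature_set, presets = cfg$presets,
      folds = cfg$folds, seed = cfg$seed,
      positive_class = cfg$positive_class, simulate = cfg$simulate,
      n_nsr = cfg$n_nsr, n_chf = cfg$n_chf, n_samples = cfg$n_samples,
      seed_derivation = "subject_seed = ((seed %% 1000003)*10007 + 13*i) %% 2147483629 + 1; fold_seed = (seed*1009 + 7919*f) %% 2147483629"),
      mpath)
    paths <- c(fpath, spath, rpaths, mpath)
  }
  out <- list(table = table, significance = sig, cv = cvs,
              reports = reports)
  attr(out, "paths") <- paths
  out
}

#' Cross-validate a battery of presets over feature families
#'
#' One row per (feature set, preset) pair with the standard report columns,
#' sorted by decreasing total accuracy. Confusion counts are kept alongside
#' so every row can be re-derived from its own counts.
#'
#' @param cohort list of [rr_series].
#' @param feature_sets character vector of feature families.
#' @param presets character vector of preset names (default: the whole
#'   registry).
#' @param folds,seed CV parameters.
#' @param positive_class positive class for the reports.
#' @param out_csv optional path for the battery CSV.
#' @param ... passed to [assemble_table()].
#' @return data.frame with columns `FeatureSet`, `Classifier`, `TPR`, `TNR`,
#'   `PPV`, `NPV`, `TA` (percent), `AUC`, `LB`, `UP`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
benchmark_battery <- function(cohort, feature_sets = "combined",
                              presets = names(preset_registry()),
                              folds = 10, seed = 0,
                              positive_class = "NSR", out_csv = NULL,
                              ...) {
  if (length(presets) < 2)
    stop("a battery needs at least two presets", call. = FALSE)
  rows <- list()
  for (fs in feature_sets) {
    table <- assemble_table(cohort, fs, ...)
    for (pr in presets) {
      s <- summary(crossvalidate(table, pr, k = folds, seed = seed,
                                 positive_class = positive_class))
      rows[[length(rows) + 1L]] <- data.frame(
        FeatureSet = fs, Classifier = pr,
        TPR = 100 * s$metrics[["TPR"]], TNR = 100 * s$metrics[["TNR"]],
        PPV = 100 * s$metrics[["PPV"]], NPV = 100 * s$metrics[["NPV"]],
        TA = 100 * s$metrics[["TA"]], AUC = s$auc,
        LB = s$ci[["CI_low"]], UP = s$ci[["CI_high"]],
        tp = s$confusion$tp, fp = s$confusion$fp,
        fn = s$confusion$fn, tn = s$confusion$tn,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$TA, out$FeatureSet, out$Classifier), ]
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
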