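#' Construct an RR-interval series
#'
#' An `rr_series` holds one subject's tachogram: the sequence of RR
#' (interbeat) intervals in seconds, a class label, and the derived beat
#' occurrence times `t` with `t[1] = 0` and `t[i]` the cumulative sum of the
#' preceding intervals.
#'
#' @param intervals numeric vector of RR intervals, seconds; all must be
#'   positive and finite.
#' @param subject_id character scalar identifying the subject.
#' @param label class label, one of `"NSR"`, `"CHF"`, `"UNKNOWN"`.
#' @return an object of class `rr_series` with fields `subject_id`, `label`,
#'   `intervals` and `t`.
#' @examples
#' s <- rr_series(c(0.8, 0.9, 1.0))
#' s$t  # 0.0 0.8 1.7
#' @export
rr_series <- function(intervals, subject_id = "subject", label = "UNKNOWN") {
  label <- match.arg(label, c("UNKNOWN", "NSR", "CHF"))
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("no samples", call. = FALSE)
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("RR intervals must be positive and finite", call. = FALSE)
  n <- length(intervals)
  structure(
    list(subject_id = as.character(subject_id), label = label,
         intervals = intervals,
         t = c(0, cumsum(intervals[-n]))),
    class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series '%s' [%s]: %d intervals, %.1f s, mean RR %.3f s\n",
              x$subject_id, x$label, length(x$intervals),
              sum(x$intervals), mean(x$intervals)))
  invisible(x)
}

#' @export
length.rr_series <- function(x) length(x$intervals)

#' Read an RR-interval text file
#'
#' Expects one numeric interval per line. Blank lines are skipped and lines
#' beginning with `#` are treated as comments (some annotated exports carry
#' them). Intervals may be recorded in seconds or milliseconds; the latter are
#' converted on read.
#'
#' @param path file path.
#' @param label class label for the subject.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param unit `"s"` (default) or `"ms"`.
#' @return an [rr_series].
#' @export
read_rr_text <- function(path, label = "UNKNOWN", subject_id = NULL,
                         unit = c("s", "ms")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  if (!any(keep)) stop("no samples", call. = FALSE)
  vals <- suppressWarnings(as.numeric(trimmed[keep]))
  lineno <- which(keep)
  bad <- which(is.na(vals) | !is.finite(vals) | vals <= 0)
  if (length(bad))
    stop(sprintf("malformed RR file '%s' at line %d: '%s'",
                 path, lineno[bad[1]], trimmed[keep][bad[1]]), call. = FALSE)
  if (unit == "ms") vals <- vals / 1000
  rr_series(vals, subject_id = subject_id, label = label)
}

#' Write an RR-interval series to a text file
#'
#' One interval per line, seconds, with enough digits to round-trip
#' bit-identically through [read_rr_text()].
#'
#' @param s an [rr_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rr_text <- function(s, path) {
  stopifnot(inherits(s, "rr_series"))
  writeLines(sprintf("%.17g", s$intervals), path)
  invisible(path)
}

#' Truncate an RR series to its first n intervals
#'
#' Long ambulatory recordings are cut to a common length (20,000 beats by
#' default) so feature magnitudes are comparable across subjects. Occurrence
#' times are recomputed. A warning is issued for recordings shorter than `n`,
#' which are kept as-is.
#'
#' @param s an [rr_series].
#' @param n number of intervals to keep (default 20000).
#' @return an [rr_series] of length `min(n, length(s))`.
#' @export
truncate_series <- function(s, n = 20000) {
  stopifnot(inherits(s, "rr_series"))
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  len <- length(s$intervals)
  if (len < n) {
    warning(sprintf("series '%s' has only %d intervals (< %d); kept as-is",
                    s$subject_id, len, n), call. = FALSE)
    n <- len
  }
  rr_series(s$intervals[seq_len(n)], subject_id = s$subject_id,
            label = s$label)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with header `path,subject_id,label` mapping RR files to
#' subjects. Labels must be `NSR` or `CHF` and subject ids unique.
#'
#' @param path manifest CSV path.
#' @return data.frame with columns `path`, `subject_id`, `label`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
}

validate_manifest <- function(m) {
  need <- c("path", "subject_id", "label")
  if (!all(need %in% names(m)))
    stop("manifest must have columns path, subject_id, label", call. = FALSE)
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(m$subject_id[duplicated(m$subject_id)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(m$label), c("NSR", "CHF"))
  if (length(bad))
    stop("manifest labels must be NSR or CHF; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  m[need]
}

#' Load a cohort of RR series from a manifest
#'
#' Reads every file listed in the manifest, truncates each series to `n`
#' intervals, and returns the series in manifest order. Per-file failures are
#' re-raised with the subject id attached.
#'
#' @param manifest a manifest data.frame or the path to a manifest CSV
#'   (see [read_manifest()]).
#' @param n truncation length passed to [truncate_series()].
#' @param unit interval unit of the RR files, `"s"` or `"ms"`.
#' @param base_dir optional directory against which relative manifest paths
#'   are resolved (defaults to the manifest's own directory when `manifest`
#'   is a path).
#' @return list of [rr_series].
#' @export
load_cohort <- function(manifest, n = 20000, unit = "s", base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  } else {
    manifest <- validate_manifest(manifest)
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!is.null(base_dir) && !file.exists(p)) p <- file.path(base_dir, p)
    tryCatch(
      truncate_series(read_rr_text(p, label = manifest$label[i],
                                   subject_id = manifest$subject_id[i],
                                   unit = unit), n = n),
      error = function(e)
        stop(sprintf("subject '%s': %s", manifest$subject_id[i],
                     conditionMessage(e)), call. = FALSE))
  })
}

#' Write a cohort to a directory of RR files plus manifest.csv
#'
#' @param cohort list of [rr_series].
#' @param dir output directory, created if missing.
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort, function(s) paste0(s$subject_id, ".txt"), "")
  for (i in seq_along(cohort))
    write_rr_text(cohort[[i]], file.path(dir, paths[i]))
  m <- data.frame(path = paths,
                  subject_id = vapply(cohort, `[[`, "", "subject_id"),
                  label = vapply(cohort, `[[`, "", "label"),
                  stringsAsFactors = FALSE)
  utils::write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}
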