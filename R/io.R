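# Plain-text CSV interfaces.  Full double precision ("%.17g"), fixed
# column order and "." decimal separator throughout, so outputs are
# diffable across runs with the same seed.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a four-channel recording as CSV
#'
#' One file per recording: header `ch1,ch2,ch3,ch4`, one row per time
#' sample, full double precision (the write/read round trip is lossless).
#'
#' @param rec A [ppg_recording()].
#' @param path Output CSV path.
#' @return `write_recording()` returns `path` invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ppg_recording"))
  m <- t(rec$samples)
  lines <- c("ch1,ch2,ch3,ch4",
             apply(m, 1L, function(r) paste(fmt_num(r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_recording
#' @param fs,glucose,subject_id,timestamp Recording metadata (not stored in
#'   the sample CSV; normally supplied from the manifest).
#' @return `read_recording()` returns a [ppg_recording()].
#' @export
read_recording <- function(path, fs = 50, glucose = NA, subject_id = "S00",
                           timestamp = "") {
  df <- utils::read.csv(path)
  if (ncol(df) != 4L)
    stop("recording CSV must have exactly 4 columns, got ", ncol(df),
         " in ", path, call. = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("recording CSV contains non-numeric cells in ", path, call. = FALSE)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path), call. = FALSE)
  ppg_recording(t(m), fs = fs, glucose = glucose,
                subject_id = subject_id, timestamp = timestamp)
}

#' Write / read a dataset manifest
#'
#' The manifest lists one row per recording: `recording_path` (relative to
#' the manifest's directory), `glucose`, `unit` (`mmol/L` or `mg/dL`),
#' `subject_id`, `timestamp`.
#'
#' @param recs List of [ppg_recording()]s.
#' @param dir Output directory (created if needed); recordings are written
#'   as `rec-0001.csv`, ... plus `manifest.csv`.
#' @return `write_dataset()` returns the manifest path invisibly.
#' @export
write_dataset <- function(recs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("rec-%04d.csv", seq_along(recs))
  for (i in seq_along(recs))
    write_recording(recs[[i]], file.path(dir, files[i]))
  man <- data.frame(recording_path = files,
                    glucose = vapply(recs, function(r)
                      fmt_num(r$glucose), character(1)),
                    unit = "mmol/L",
                    subject_id = vapply(recs, function(r)
                      r$subject_id, character(1)),
                    timestamp = vapply(recs, function(r)
                      r$timestamp, character(1)))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @param path Path to a `manifest.csv`.
#' @param fs Sampling rate attached to the recordings (Hz).
#' @return `read_dataset()` returns a list of [ppg_recording()]s.
#' @export
read_dataset <- function(path, fs = 50) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_path", "glucose", "unit", "subject_id", "timestamp")
  if (!all(need %in% names(man)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(man)), collapse = ", "), call. = FALSE)
  if (any(!man$unit %in% c("mmol/L", "mg/dL")))
    stop("manifest unit must be mmol/L or mg/dL", call. = FALSE)
  glu <- as.numeric(man$glucose)
  glu[man$unit == "mg/dL"] <- glu[man$unit == "mg/dL"] / MGDL_PER_MMOL
  if (any(!is.finite(glu)) || any(glu <= 0))
    stop("manifest glucose values must be positive numbers", call. = FALSE)
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i)
    read_recording(file.path(base, man$recording_path[i]), fs = fs,
                   glucose = glu[i], subject_id = man$subject_id[i],
                   timestamp = man$timestamp[i]))
}

#' Write / read a feature table
#'
#' CSV with the 16 feature columns in the fixed flattening order
#' `XM_r ... XM_z, XK_r ... XK_z, XO_r ... XO_z, XG_r ... XG_z`, plus a
#' `glucose` column (mmol/L; `NA` allowed for unlabeled data).  The header
#' is validated on read.
#'
#' @param featuresets List of `"median_features"` (or a 16-column matrix).
#' @param path Output CSV path.
#' @param glucose Optional targets; defaults to the glucose carried by the
#'   feature sets.
#' @return `write_features()` returns `path` invisibly.
#' @export
write_features <- function(featuresets, path, glucose = NULL) {
  if (is.matrix(featuresets)) {
    m <- featuresets
  } else if (length(featuresets) == 0L) {
    m <- matrix(numeric(0), nrow = 0L, ncol = 16L)
    glucose <- numeric(0)
  } else {
    m <- feature_matrix(featuresets)
    if (is.null(glucose))
      glucose <- vapply(featuresets, function(f)
        if (is.null(f$glucose)) NA_real_ else f$glucose, numeric(1))
  }
  if (ncol(m) != 16L) stop("feature matrix must have 16 columns",
                           call. = FALSE)
  if (is.null(glucose)) glucose <- rep(NA_real_, nrow(m))
  header <- paste(c(FEATURE_NAMES, "glucose"), collapse = ",")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(fmt_num(m[i, ]),
            if (is.na(glucose[i])) "NA" else fmt_num(glucose[i])),
          collapse = ","), character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_features
#' @return `read_features()` returns a list with `x` (matrix, 16 named
#'   columns) and `glucose` (numeric vector, possibly `NA`).
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df)[1:16], FEATURE_NAMES))
    stop("feature CSV header does not match the expected column order",
         call. = FALSE)
  x <- as.matrix(df[FEATURE_NAMES])
  if (nrow(df) == 0L)
    return(list(x = x, glucose = numeric(0)))
  list(x = x, glucose = as.numeric(df$glucose))
}

#' Write a metrics report as JSON
#'
#' Schema: `{mae, rmse, mard, n, unit, clarke: {counts: {A..E},
#' pct: {A..E}}}`.
#'
#' @param report A [metrics_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  obj <- list(mae = report$mae, rmse = report$rmse, mard = report$mard,
              n = report$n, unit = report$unit,
              clarke = list(counts = as.list(report$clarke_counts),
                            pct = as.list(report$clarke_pct)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
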