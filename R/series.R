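# subject_series container and temporal preprocessing

#' Create a subject series
#'
#' A `subject_series` is a numeric ROI-by-frame matrix (rows = regions,
#' columns = frames) tagged with the subject it belongs to, the longitudinal
#' timepoint, the sampling interval (TR, seconds) and the space the rows live
#' in (`"source"` for ROI signals, `"latent"` for autoencoder dimensions).
#'
#' @param data numeric matrix, regions x frames; at least 2 frames, no
#'   missing values.
#' @param subject_id character scalar.
#' @param timepoint one of `"2wk"`, `"3mo"`, `"1yr"`, `"control"`.
#' @param tr repetition time in seconds (default 2, typical of fMRI).
#' @param space `"source"` or `"latent"`.
#' @return a `subject_series` object.
#' @export
subject_series <- function(data, subject_id = "s1",
                           timepoint = c("control", "2wk", "3mo", "1yr"),
                           tr = 2, space = c("source", "latent")) {
  timepoint <- match.arg(timepoint)
  space <- match.arg(space)
  abort_if(!is.matrix(data) || !is.numeric(data), "data must be a numeric matrix")
  abort_if(ncol(data) < 2, "a series needs at least 2 frames")
  abort_if(anyNA(data) || any(!is.finite(data)), "series contains missing or non-finite values")
  structure(data,
            subject_id = as.character(subject_id), timepoint = timepoint,
            tr = tr, space = space, class = "subject_series")
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("<subject_series> %s @ %s [%s space], %d x %d, TR = %gs\n",
              attr(x, "subject_id"), attr(x, "timepoint"), attr(x, "space"),
              nrow(x), ncol(x), attr(x, "tr")))
  invisible(x)
}

with_series_tags <- function(data, template) {
  subject_series(data,
                 subject_id = series_tag(template, "subject_id", "s1"),
                 timepoint = series_tag(template, "timepoint", "control"),
                 tr = series_tag(template, "tr", 2),
                 space = series_tag(template, "space", "source"))
}

#' Read / write a series matrix as delimited text
#'
#' Series are stored as plain tab-separated matrices (rows = regions,
#' columns = frames) with a JSON sidecar `<path>.json` carrying the
#' subject/timepoint/TR/space tags. `read_series()` validates rectangularity
#' and reports the location of any non-numeric cell.
#'
#' @param path file path of the matrix.
#' @param series a `subject_series`.
#' @return `read_series()` returns a `subject_series`; `write_series()`
#'   returns `path` invisibly.
#' @export
read_series <- function(path) {
  abort_if(!file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  abort_if(length(lines) == 0, "empty series file")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("format error: ragged row %d (%d cells, expected %d)",
                 bad, widths[bad], widths[1]), call. = FALSE)
  }
  vals <- suppressWarnings(lapply(cells, as.numeric))
  for (i in seq_along(vals)) {
    if (anyNA(vals[[i]])) {
      j <- which(is.na(vals[[i]]))[1]
      stop(sprintf("parse error: non-numeric cell at row %d, column %d ('%s')",
                   i, j, cells[[i]][j]), call. = FALSE)
    }
  }
  m <- do.call(rbind, vals)
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  subject_series(m,
                 subject_id = meta$subject_id %||% "s1",
                 timepoint = meta$timepoint %||% "control",
                 tr = meta$tr %||% 2,
                 space = meta$space %||% "source")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_series
#' @export
write_series <- function(series, path) {
  m <- as_series_matrix(series)
  # 17 significant digits round-trips doubles exactly
  lines <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  meta <- list(subject_id = series_tag(series, "subject_id", "s1"),
               timepoint = series_tag(series, "timepoint", "control"),
               tr = series_tag(series, "tr", 2),
               space = series_tag(series, "space", "source"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Zero-phase band-pass filter
#'
#' Applies a second-order Butterworth band-pass forward and backward
#' (zero phase) independently to each row, the standard temporal filter for
#' resting-state signals; the conventional band is 0.009--0.08 Hz.
#'
#' @param series a `subject_series` (TR tag sets the sampling rate) or matrix.
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1/(2*tr)`.
#' @param tr sampling interval in seconds, used when `series` is a bare matrix.
#' @return filtered series, same shape and tags.
#' @export
bandpass <- function(series, low_hz = 0.009, high_hz = 0.08, tr = NULL) {
  m <- as_series_matrix(series)
  tr <- tr %||% series_tag(series, "tr", 2)
  nyq <- 1 / (2 * tr)
  abort_if(low_hz < 0 || low_hz >= high_hz, "need 0 <= low_hz < high_hz")
  abort_if(high_hz >= nyq,
           sprintf("high_hz (%g) must be below Nyquist (%g Hz)", high_hz, nyq))
  flt <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  # demean first: the band excludes DC, and removing it up front avoids
  # filter edge transients on strongly offset rows
  out <- t(apply(m - rowMeans(m), 1, function(r) signal::filtfilt(flt, r)))
  if (inherits(series, "subject_series")) with_series_tags(out, series) else out
}

#' Z-score each row with the population standard deviation
#'
#' Rows are centred and scaled by the divide-by-n standard deviation. This
#' normalisation is load-bearing: it makes the time average of an edge
#' co-fluctuation series equal the Pearson correlation exactly.
#'
#' @param series a `subject_series` or numeric matrix.
#' @return the row-standardised series, same shape and tags.
#' @export
zscore_rows <- function(series) {
  m <- as_series_matrix(series)
  mu <- rowMeans(m)
  s <- sqrt(rowMeans((m - mu)^2))
  if (any(s == 0)) {
    stop(sprintf("zero-variance row(s): %s",
                 paste(which(s == 0), collapse = ", ")), call. = FALSE)
  }
  out <- (m - mu) / s
  if (inherits(series, "subject_series")) with_series_tags(out, series) else out
}

#' Concatenate a cohort's series into one training matrix
#'
#' Each subject's series at the requested timepoint is row z-scored and the
#' frames are concatenated subject by subject, producing the
#' regions x (frames x subjects) matrix the autoencoder trains on, together
#' with an index map that inverts the concatenation.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param timepoint `"acute"` (controls' resting series plus patients' 2-week
#'   series; the default) or one of `"control"`, `"2wk"`, `"3mo"`, `"1yr"`.
#' @return list with `frames` (matrix) and `index` (tibble: subject_id,
#'   start, end column of that subject's block).
#' @export
concatenate_for_training <- function(cohort, timepoint = "acute") {
  stopifnot(inherits(cohort, "bold_cohort"))
  sel <- cohort_series_keys(cohort, timepoint)
  abort_if(length(sel) == 0, "no series match the requested timepoint")
  mats <- lapply(sel, function(k) zscore_rows(cohort$series[[k]]))
  nroi <- vapply(mats, nrow, 1L)
  abort_if(length(unique(nroi)) > 1, "shape error: series have mixed region counts")
  nf <- vapply(mats, ncol, 1L)
  end <- cumsum(nf)
  idx <- tibble::tibble(
    subject_id = vapply(sel, function(k) series_tag(cohort$series[[k]], "subject_id", k), ""),
    start = c(1L, head(end, -1) + 1L), end = end)
  list(frames = do.call(cbind, lapply(mats, as_series_matrix)), index = idx)
}

# keys of the series map matching a timepoint request
cohort_series_keys <- function(cohort, timepoint) {
  tps <- vapply(cohort$series, function(s) series_tag(s, "timepoint", ""), "")
  if (identical(timepoint, "acute")) {
    names(tps)[tps %in% c("control", "2wk")]
  } else {
    names(tps)[tps == timepoint]
  }
}
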