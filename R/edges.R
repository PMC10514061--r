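# edge-centric decomposition of functional connectivity

#' Edge co-fluctuation time series
#'
#' Unwraps the Pearson correlation over time: after row z-scoring with the
#' population SD, the edge series of regions i and j is the frame-wise
#' product `e_ij(t) = z_i(t) * z_j(t)`. Its time average equals the Pearson
#' correlation r_ij exactly, so edge series decompose each functional
#' connection into frame-wise contributions without any windowing.
#'
#' @param series a `subject_series` or matrix with >= 2 frames.
#' @return an `edge_series`: matrix `n_edges x n_frames` with attribute
#'   `edge_index`, a tibble mapping row k to its region pair (i < j).
#' @export
edge_time_series <- function(series) {
  z <- as_series_matrix(zscore_rows(series))
  n <- nrow(z)
  abort_if(n < 2, "need at least 2 regions")
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)  # column-major i<j order
  e <- z[pairs[, 1], , drop = FALSE] * z[pairs[, 2], , drop = FALSE]
  structure(e,
            edge_index = tibble::tibble(edge = seq_len(nrow(pairs)),
                                        i = pairs[, 1], j = pairs[, 2]),
            space = series_tag(series, "space", "source"),
            class = "edge_series")
}

#' Root-sum-square co-fluctuation amplitude
#'
#' The collective co-fluctuation at each frame:
#' `RSS(t) = sqrt(sum_k e_k(t)^2)` over all edges. Transient peaks of this
#' trace are candidate network "events".
#'
#' @param edges an `edge_series` (or any edges-x-frames matrix).
#' @return nonnegative numeric vector, one value per frame.
#' @export
edge_rss <- function(edges) {
  m <- if (inherits(edges, "edge_series")) unclass_matrix(edges) else edges
  sqrt(colSums(m^2))
}

# RSS directly from a z-scored series, without forming the edge matrix:
# sum_{i<j} (z_i z_j)^2 = ((sum z^2)^2 - sum z^4) / 2
rss_from_z <- function(z) {
  s2 <- colSums(z^2)
  s4 <- colSums(z^4)
  sqrt(pmax(0, (s2^2 - s4) / 2))
}

#' Circular-shift null distribution of the RSS trace
#'
#' Each iteration circularly rotates every region's time series by an
#' independent uniform offset (preserving each region's autocorrelation and
#' exact value multiset while destroying cross-region alignment), then
#' recomputes the RSS trace.
#'
#' @param series a `subject_series` or matrix.
#' @param n_iter number of null iterations (the reference protocol uses
#'   1000).
#' @param seed integer seed; fixed seed reproduces the sample exactly.
#' @return matrix `n_iter x n_frames` of null RSS values.
#' @export
circshift_null <- function(series, n_iter = 1000, seed = 1) {
  abort_if(n_iter < 1, "n_iter must be >= 1")
  z <- as_series_matrix(zscore_rows(series))
  n <- nrow(z)
  tt <- ncol(z)
  set.seed(seed)
  out <- matrix(0, n_iter, tt)
  for (it in seq_len(n_iter)) {
    shifts <- sample.int(tt, n, replace = TRUE) - 1L
    out[it, ] <- rss_from_z(circshift_rows(z, shifts))
  }
  out
}

# circularly rotate each row r of z to the right by shifts[r] frames
circshift_rows <- function(z, shifts) {
  tt <- ncol(z)
  for (r in seq_len(nrow(z))) {
    k <- shifts[r] %% tt
    if (k > 0) z[r, ] <- z[r, c((tt - k + 1):tt, 1:(tt - k))]
  }
  z
}

#' Detect significant co-fluctuation events
#'
#' Frames whose empirical RSS exceeds the `(1 - p)` quantile of the pooled
#' circular-shift null are flagged as events. Flagged frames whose RSS
#' z-score relative to the trace's own mean and SD exceeds `z_max` in
#' magnitude are moved to an excluded set (extreme outliers are not treated
#' as physiological events).
#'
#' @param rss_trace empirical RSS vector.
#' @param null_sample matrix from [circshift_null()].
#' @param p pooled-null tail probability (default 0.001).
#' @param z_max exclusion threshold on the trace's own z-score (default 4.5).
#' @return a `peak_set`: list with `peaks` (flagged frame indices, 1-based),
#'   `excluded`, `threshold`, `rss`, `n_frames`, `p`, `z_max`.
#' @export
detect_peaks <- function(rss_trace, null_sample, p = 0.001, z_max = 4.5) {
  abort_if(p <= 0 || p >= 0.5, "p must lie in (0, 0.5)")
  abort_if(length(null_sample) == 0, "null_sample is empty")
  thr <- quantile(as.numeric(null_sample), probs = 1 - p, names = FALSE)
  flagged <- which(rss_trace > thr)
  z <- (rss_trace - mean(rss_trace)) / sd(rss_trace)
  excl <- flagged[abs(z[flagged]) > z_max]
  structure(list(peaks = setdiff(flagged, excl), excluded = excl,
                 threshold = thr, rss = rss_trace,
                 n_frames = length(rss_trace), p = p, z_max = z_max),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d/%d frames flagged (%d excluded), threshold %.3f\n",
              length(x$peaks), x$n_frames, length(x$excluded), x$threshold))
  invisible(x)
}

#' Event detection on a series in one call
#'
#' Convenience wrapper: edge RSS, circular-shift null, and peak detection.
#'
#' @inheritParams circshift_null
#' @inheritParams detect_peaks
#' @return a `peak_set`.
#' @export
detect_events <- function(series, n_iter = 1000, p = 0.001, z_max = 4.5,
                          seed = 1) {
  z <- as_series_matrix(zscore_rows(series))
  detect_peaks(rss_from_z(z), circshift_null(series, n_iter, seed),
               p = p, z_max = z_max)
}

#' Functional connectivity from selected frames
#'
#' Pearson correlation matrix computed on a subset of frames only, e.g. the
#' event frames of a [detect_peaks()] set. With all frames selected this is
#' the full FC matrix.
#'
#' @param series a `subject_series` or matrix.
#' @param frames integer frame indices (1-based), at least 2.
#' @return a `conn_matrix` of kind `"FC"`.
#' @export
fc_from_frames <- function(series, frames) {
  m <- as_series_matrix(series)
  abort_if(length(frames) < 2, "need at least 2 frames to compute FC")
  abort_if(any(frames < 1 | frames > ncol(m)), "frame index out of range")
  sub <- m[, frames, drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate frame selection: zero variance in region(s) %s",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  }
  conn_matrix(cor(t(sub)), kind = "FC")
}

#' Agreement between two event sets
#'
#' `hits / (hits + miss)`, where hits are frames flagged in both sets and
#' miss are frames flagged in exactly one. Two empty sets agree perfectly
#' (defined as 1). Frame matching is exact (no tolerance).
#'
#' @param peaks_a,peaks_b `peak_set`s from equal-length traces.
#' @return agreement in `[0, 1]`.
#' @export
peak_agreement <- function(peaks_a, peaks_b) {
  stopifnot(inherits(peaks_a, "peak_set"), inherits(peaks_b, "peak_set"))
  abort_if(peaks_a$n_frames != peaks_b$n_frames,
           "peak sets come from traces of different lengths")
  a <- peaks_a$peaks
  b <- peaks_b$peaks
  hits <- length(intersect(a, b))
  miss <- length(setdiff(a, b)) + length(setdiff(b, a))
  if (hits + miss == 0) return(1)
  hits / (hits + miss)
}

#' Source-latent peak agreement across bottleneck dimensions
#'
#' For every subject and every trained model, events are detected on the
#' source RSS trace and on the latent RSS trace (after encoding), and their
#' [peak_agreement()] is recorded. Consecutive dimensions are compared with
#' a paired t-test over subjects.
#'
#' @param cohort a `bold_cohort`.
#' @param models named list of trained [train_autoencoder()] models, one per
#'   bottleneck dimension.
#' @param n_iter,p,z_max event-detection settings.
#' @param seed integer seed for the null models.
#' @param timepoint which series to analyse (default `"acute"`).
#' @return an `agreement_curve`: list with `by_subject` (tibble: d,
#'   subject_id, agreement), `curve` (tibble: d, mean, sd), `steps`
#'   (tibble: paired t between consecutive d).
#' @export
agreement_curve <- function(cohort, models, n_iter = 200, p = 0.001,
                            z_max = 4.5, seed = 1, timepoint = "acute") {
  keys <- cohort_series_keys(cohort, timepoint)
  ds <- vapply(models, function(m) m$d, 1L)
  rows <- list()
  for (k in seq_along(keys)) {
    s <- cohort$series[[keys[k]]]
    src <- detect_events(s, n_iter, p, z_max, seed = derive_seed(seed, k))
    for (mi in seq_along(models)) {
      lat <- encode_series(models[[mi]], s)
      lp <- detect_events(lat, n_iter, p, z_max,
                          seed = derive_seed(seed, 1000 * mi + k))
      rows[[length(rows) + 1]] <- tibble::tibble(
        d = ds[mi],
        subject_id = series_tag(s, "subject_id", keys[k]),
        agreement = peak_agreement(src, lp))
    }
  }
  by_subject <- dplyr::bind_rows(rows)
  curve <- dplyr::summarise(dplyr::group_by(by_subject, .data$d),
                            mean = mean(.data$agreement),
                            sd = sd(.data$agreement), .groups = "drop")
  ds_sorted <- sort(unique(by_subject$d))
  steps <- NULL
  if (length(ds_sorted) > 1) {
    step_rows <- lapply(seq_len(length(ds_sorted) - 1), function(i) {
      a <- by_subject$agreement[by_subject$d == ds_sorted[i]]
      b <- by_subject$agreement[by_subject$d == ds_sorted[i + 1]]
      if (sd(b - a) == 0) {
        tibble::tibble(d_from = ds_sorted[i], d_to = ds_sorted[i + 1],
                       statistic = 0, p.value = 1)
      } else {
        tt <- t.test(b, a, paired = TRUE)
        tibble::tibble(d_from = ds_sorted[i], d_to = ds_sorted[i + 1],
                       statistic = unname(tt$statistic),
                       p.value = tt$p.value)
      }
    })
    steps <- dplyr::bind_rows(step_rows)
  }
  structure(list(by_subject = by_subject, curve = curve, steps = steps),
            class = "agreement_curve")
}
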