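# temporal irreversibility (non-equilibrium) of multivariate series

#' Time-shifted Pearson correlation
#'
#' The forward lagged correlation between two series:
#' `cor(x(t), y(t + dt))` over the overlapping frames.
#'
#' @param x,y numeric series of equal length.
#' @param dt positive integer shift in frames.
#' @return Pearson correlation of the lagged pairs.
#' @export
shifted_correlation <- function(x, y, dt = 1) {
  abort_if(length(x) != length(y), "series lengths differ")
  abort_if(dt < 1 || dt >= length(x), "need 1 <= dt < length(x)")
  a <- x[seq_len(length(x) - dt)]
  b <- y[(dt + 1):length(y)]
  abort_if(sd(a) == 0 || sd(b) == 0,
           "undefined correlation: constant subseries")
  cor(a, b)
}

#' Reverse the time ordering of a series
#'
#' `x_r(t) = x(T - 1 - t)`; applying it twice restores the input.
#'
#' @param x numeric vector.
#' @return the time-reversed vector.
#' @export
reverse_series <- function(x) rev(x)

#' Pairwise irreversibility matrix
#'
#' For every region pair, the forward lagged correlation
#' `C_f = cor(x_i(t), x_j(t + dt))` is compared with the same quantity
#' computed on the time-reversed pair of series, and the irreversibility is
#' their absolute difference `I_ij = |C_f - C_r|`. Reversing both series
#' turns the lag around, so `C_r(i, j) = C_f(j, i)`: the matrix is symmetric
#' with an exactly zero diagonal (lag-dt autocorrelation is
#' reversal-invariant), and a reversible (equilibrium) process gives I near
#' 0 while asymmetric directed drive raises it. The default shift is one
#' frame, the minimum step that avoids choosing a window duration.
#'
#' @param series a `subject_series` or matrix (regions x frames).
#' @param dt shift in frames (default 1).
#' @return an `irreversibility_matrix` (a `conn_matrix` of kind
#'   `"irreversibility"` with a `dt` attribute).
#' @export
irreversibility_matrix <- function(series, dt = 1) {
  m <- as_series_matrix(series)
  tt <- ncol(m)
  abort_if(tt <= dt, "series must be longer than dt")
  a <- t(m[, seq_len(tt - dt), drop = FALSE])
  b <- t(m[, (dt + 1):tt, drop = FALSE])
  sds <- c(apply(a, 2, sd), apply(b, 2, sd))
  if (any(sds == 0)) {
    bad <- unique((which(sds == 0) - 1) %% nrow(m) + 1)
    stop(sprintf("undefined correlation: constant subseries in region(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fwd <- cor(a, b)  # fwd[i, j] = cor(x_i(t), x_j(t + dt))
  out <- abs(fwd - t(fwd))
  diag(out) <- 0
  res <- conn_matrix(out, kind = "irreversibility")
  attr(res, "dt") <- dt
  attr(res, "space") <- series_tag(series, "space", "source")
  res
}

#' Mean irreversibility
#'
#' The average of the strict upper triangle of an irreversibility matrix:
#' the scalar non-equilibrium summary used for group comparison and as a
#' classification feature.
#'
#' @param matrix an `irreversibility_matrix` (or square matrix).
#' @return nonnegative scalar.
#' @export
mean_irreversibility <- function(matrix) {
  mean(upper_tri(if (inherits(matrix, "conn_matrix")) unclass_matrix(matrix)
                 else matrix))
}
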