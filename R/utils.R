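# shared internal helpers

#' Extract the strict upper triangle of a square matrix
#'
#' Values are returned column-major, the order used everywhere a matrix is
#' vectorised into features.
#'
#' @param m square matrix.
#' @return numeric vector of length `n*(n-1)/2`.
#' @export
upper_tri <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[upper.tri(m)]
}

# deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer and independent-ish across keys
derive_seed <- function(seed, key) {
  s <- (as.numeric(seed) * 48271 + as.numeric(key) * 16807) %% 2147483647
  as.integer(s) + 1L
}

# population (divide-by-n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

as_series_matrix <- function(series) {
  if (inherits(series, "subject_series")) unclass_series(series) else {
    abort_if(!is.matrix(series) || !is.numeric(series),
             "expected a subject_series or a numeric matrix")
    series
  }
}

unclass_series <- function(series) {
  m <- series
  attributes(m) <- list(dim = dim(series))
  m
}

series_tag <- function(series, what, default) {
  v <- attr(series, what, exact = TRUE)
  if (is.null(v)) default else v
}
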