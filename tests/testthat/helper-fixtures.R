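# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small but fully featured cohort: quick to simulate, big enough for
# group statistics and median splits
tiny_cohort <- function() {
  cached("tiny_cohort", generate_cohort(
    cohort_params(n_controls = 6, n_patients = 10, n_roi = 10,
                  n_frames = 120), seed = 42))
}

# the default desk-profile cohort (50 ROI x 400 frames, 30 + 60)
desk_cohort <- function() {
  cached("desk_cohort", generate_cohort(cohort_params(), seed = 1))
}

# frames on an exact 3-dimensional linear subspace of a 20-ROI space
subspace_frames <- function(n = 3000, seed = 7) {
  set.seed(seed)
  b <- matrix(rnorm(20 * 3), 20, 3)
  b %*% matrix(rnorm(3 * n), 3, n)
}

# 4 latent sinusoidal drivers mixed through a squashing nonlinearity
# into 20 ROIs: a planted 4-dimensional nonlinear manifold
manifold_frames <- function(n = 4000, seed = 3) {
  set.seed(seed)
  tt <- seq(0, 60, length.out = n)
  drivers <- rbind(sin(2 * pi * 0.11 * tt), sin(2 * pi * 0.23 * tt + 1),
                   sin(2 * pi * 0.05 * tt + 2), sin(2 * pi * 0.31 * tt))
  mix <- matrix(rnorm(20 * 4, sd = 2.5), 20, 4)
  tanh(mix %*% drivers) + matrix(rnorm(20 * n, sd = 0.05), 20, n)
}

# an autoencoder object that embeds identically (d = n_roi, identity maps);
# bypasses training to give an exact identity-embedding control
identity_model <- function(n_roi) {
  structure(list(
    layers = list(list(W = diag(n_roi), b = rep(0, n_roi)),
                  list(W = diag(n_roi), b = rep(0, n_roi))),
    acts = c(FALSE, FALSE), widths = rep(n_roi, 3), d = as.integer(n_roi),
    bottleneck = 1L, history = NULL, val_idx = integer(0), seed = 0L,
    hyper = ae_hyper(), best_epoch = 0L, val_loss = 0, val_correlation = 1,
    trained = TRUE), class = "latent_ae")
}

# brute-force best constant-Potts bipartition quality over all 2^(n-1)
# splits (node 1 fixed); independent oracle for the Louvain optimiser
brute_best_bipartition <- function(w, gamma) {
  n <- nrow(w)
  a <- w - gamma
  diag(a) <- 0
  denom <- sum(abs(w)[row(w) != col(w)])
  best_q <- -Inf
  best_memb <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {
    x <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    q <- (crossprod(x, a %*% x) + crossprod(1 - x, a %*% (1 - x))) / denom
    if (q > best_q) {
      best_q <- as.numeric(q)
      best_memb <- x + 1L
    }
  }
  list(quality = best_q, membership = best_memb)
}
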