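# VAR(1) coupling construction, stroke-like lesioning, and simulation

#' Build a modular, hemisphere-paired VAR(1) coupling matrix
#'
#' Constructs the directed coefficient matrix of a first-order vector
#' autoregression with planted community structure and homotopic
#' (left-right mirror pair) connections, plus an optional antisymmetric
#' perturbation that makes the dynamics temporally irreversible. Regions
#' `1..n_roi/2` form the left hemisphere and region `i` is homotopic to
#' region `i + n_roi/2`. Modules are assigned contiguously and mirrored
#' across hemispheres. The matrix is rescaled so its spectral radius equals
#' `target_radius`, guaranteeing stationarity.
#'
#' @param n_roi even number of regions.
#' @param n_modules number of planted modules (>= 2).
#' @param within_w,between_w,homotopic_w block weights before rescaling.
#' @param asymmetry standard deviation of the antisymmetric perturbation
#'   added to off-diagonal entries; 0 gives an exactly symmetric matrix.
#' @param target_radius spectral radius after rescaling, in (0, 1).
#' @param seed integer seed for the random perturbation.
#' @return a `coupling_matrix`: list with `weights`, `modules`,
#'   `hemispheres`, `target_radius`.
#' @export
build_coupling <- function(n_roi = 50, n_modules = 2, within_w = 1,
                           between_w = 0.1, homotopic_w = 0.5,
                           asymmetry = 0.05, target_radius = 0.85,
                           seed = 1) {
  abort_if(n_roi %% 2 != 0, "n_roi must be even (hemisphere pairing)")
  abort_if(n_modules < 2, "need at least 2 modules")
  abort_if(target_radius <= 0 || target_radius >= 1,
           "target_radius must lie in (0, 1)")
  abort_if(asymmetry < 0, "asymmetry must be >= 0")
  half <- n_roi / 2
  hemi <- rep(c("left", "right"), each = half)
  mod_half <- sort(rep_len(seq_len(n_modules), half))
  modules <- c(mod_half, mod_half)  # mirrored across hemispheres

  w <- matrix(0, n_roi, n_roi)
  same_mod <- outer(modules, modules, "==")
  w[same_mod] <- within_w
  w[!same_mod] <- between_w
  homo <- cbind(seq_len(half), seq_len(half) + half)
  w[homo] <- homotopic_w
  w[homo[, 2:1]] <- homotopic_w
  diag(w) <- within_w

  if (asymmetry > 0) {
    set.seed(seed)
    a <- matrix(rnorm(n_roi^2, sd = asymmetry), n_roi, n_roi)
    a <- (a - t(a)) / sqrt(2)  # antisymmetric, entries ~ N(0, asymmetry^2)
    diag(a) <- 0
    w <- w + a
  }
  w <- rescale_radius(w, target_radius)
  structure(list(weights = w, modules = modules, hemispheres = hemi,
                 target_radius = target_radius),
            class = "coupling_matrix")
}

spectral_radius <- function(w) max(Mod(eigen(w, only.values = TRUE)$values))

rescale_radius <- function(w, target) {
  r <- spectral_radius(w)
  abort_if(r == 0, "cannot rescale a nilpotent/zero coupling to a target radius")
  w * (target / r)
}

#' Apply a stroke-like lesion to a coupling matrix
#'
#' Scales homotopic interhemispheric weights down by
#' `1 - k_homotopic * severity`, adds an extra antisymmetric perturbation
#' whose entries have standard deviation `k_asym * severity` (raising
#' temporal irreversibility), and multiplies the rows and columns of
#' `n_lesioned` randomly chosen regions by 0.1 (structural damage without
#' changing matrix shape). The result is re-capped at the original target
#' spectral radius if the lesion pushed it above.
#'
#' The lesion's antisymmetric perturbation is low-rank: it is built from
#' random directed imbalances between the module-by-hemisphere blocks
#' (`A = U C U'` with block-indicator patterns `U` and a random
#' antisymmetric coefficient matrix `C`, rescaled to the requested entry
#' SD). Post-stroke directional disruption therefore acts on the same
#' large-scale modes that carry the shared variance, rather than as
#' region-pair-independent noise -- the regime in which a low-dimensional
#' embedding can retain the irreversibility signal.
#'
#' @param coupling a `coupling_matrix`.
#' @param severity lesion severity in `[0, 1]`.
#' @param k_homotopic,k_asym effect coefficients for homotopic weight loss
#'   and added temporal asymmetry.
#' @param n_lesioned number of damaged regions (< n_roi).
#' @param lesioned optional fixed set of region indices (overrides the
#'   random draw; used to keep a subject's lesion location stable across
#'   timepoints).
#' @param seed integer seed for lesion placement and the asymmetric draw.
#' @return a lesioned `coupling_matrix`; `severity = 0, n_lesioned = 0`
#'   returns the input unchanged.
#' @export
lesion_coupling <- function(coupling, severity, k_homotopic = 0.3,
                            k_asym = 0.05, n_lesioned = 0, lesioned = NULL,
                            seed = 1) {
  stopifnot(inherits(coupling, "coupling_matrix"))
  abort_if(severity < 0 || severity > 1, "severity must lie in [0, 1]")
  n <- nrow(coupling$weights)
  abort_if(n_lesioned >= n, "n_lesioned must be smaller than n_roi")
  if (severity == 0 && n_lesioned == 0 && is.null(lesioned)) return(coupling)
  w <- coupling$weights
  half <- n / 2
  set.seed(seed)
  homo <- cbind(seq_len(half), seq_len(half) + half)
  scale_h <- 1 - k_homotopic * severity
  w[homo] <- w[homo] * scale_h
  w[homo[, 2:1]] <- w[homo[, 2:1]] * scale_h
  if (k_asym * severity > 0) {
    blocks <- interaction(coupling$modules, coupling$hemispheres, drop = TRUE)
    u <- sapply(levels(blocks), function(b) as.numeric(blocks == b))
    u <- sweep(u, 2, sqrt(colSums(u^2)), "/")
    k <- ncol(u)
    cc <- matrix(rnorm(k * k), k, k)
    cc <- cc - t(cc)
    a <- u %*% cc %*% t(u)
    diag(a) <- 0
    a <- a * (k_asym * severity) / sd_pop(a[row(a) != col(a)])
    w <- w + a
  }
  if (is.null(lesioned) && n_lesioned > 0) {
    lesioned <- sample.int(n, n_lesioned)
  }
  if (length(lesioned)) {
    w[lesioned, ] <- w[lesioned, ] * 0.1
    w[, lesioned] <- w[, lesioned] * 0.1
  }
  if (spectral_radius(w) > coupling$target_radius) {
    w <- rescale_radius(w, coupling$target_radius)
  }
  out <- coupling
  out$weights <- w
  out$lesioned <- sort(as.integer(lesioned %||% integer(0)))
  out
}

#' Simulate a BOLD-like series from a VAR(1) coupling
#'
#' Iterates `x(t+1) = W x(t) + eps`, `eps ~ N(0, noise_sd^2 I)`, discards
#' `burn_in` initial frames, and returns the remaining `n_frames` frames as
#' a `subject_series`.
#'
#' @param coupling a `coupling_matrix` or bare coefficient matrix with
#'   spectral radius < 1.
#' @param n_frames frames to keep (>= 2).
#' @param noise_sd innovation standard deviation.
#' @param burn_in discarded initial frames.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param subject_id,timepoint,tr tags for the returned series.
#' @return a `subject_series` of size n_roi x n_frames.
#' @export
simulate_series <- function(coupling, n_frames = 400, noise_sd = 1,
                            burn_in = 100, seed = 1, subject_id = "s1",
                            timepoint = "control", tr = 2) {
  w <- if (inherits(coupling, "coupling_matrix")) coupling$weights else coupling
  abort_if(!is.matrix(w) || nrow(w) != ncol(w), "coupling must be square")
  abort_if(n_frames < 2, "n_frames must be >= 2")
  abort_if(burn_in < 0, "burn_in must be >= 0")
  abort_if(spectral_radius(w) >= 1,
           "unstable coupling: spectral radius must be < 1")
  n <- nrow(w)
  set.seed(seed)
  total <- burn_in + n_frames
  eps <- matrix(rnorm(n * total, sd = noise_sd), n, total)
  x <- matrix(0, n, total)
  x[, 1] <- eps[, 1]
  for (t in seq_len(total - 1)) x[, t + 1] <- w %*% x[, t] + eps[, t + 1]
  out <- x[, (burn_in + 1):total, drop = FALSE]
  subject_series(out, subject_id = subject_id, timepoint = timepoint, tr = tr)
}

#' Stationary covariance of a VAR(1) process
#'
#' Solves the discrete Lyapunov equation `S = W S W' + noise_sd^2 I` by
#' vectorisation; the lag-1 cross-covariance is `W S`. Used as a closed-form
#' check on simulated series.
#'
#' @param w VAR(1) coefficient matrix (radius < 1).
#' @param noise_sd innovation standard deviation.
#' @return list with `sigma` (stationary covariance) and `lag1`
#'   (`cov(x(t+1), x(t)) = W sigma`).
#' @export
var1_stationary_cov <- function(w, noise_sd = 1) {
  n <- nrow(w)
  q <- diag(noise_sd^2, n)
  vec_s <- solve(diag(n * n) - kronecker(w, w), as.vector(q))
  sigma <- matrix(vec_s, n, n)
  list(sigma = sigma, lag1 = w %*% sigma)
}

#' First-half/second-half variance stability of a series
#'
#' A crude stationarity diagnostic: the ratio of mean row variance in the
#' second half of the recording to the first half. Values near 1 indicate a
#' stable process.
#'
#' @param series a `subject_series` or matrix.
#' @return the variance ratio (second half / first half).
#' @export
variance_stability <- function(series) {
  m <- as_series_matrix(series)
  half <- floor(ncol(m) / 2)
  v1 <- mean(apply(m[, seq_len(half), drop = FALSE], 1, var))
  v2 <- mean(apply(m[, (half + 1):ncol(m), drop = FALSE], 1, var))
  v2 / v1
}
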