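# dynamical features computed identically in source and latent space

#' Functional connectivity dynamics matrix
#'
#' FC is computed in sliding windows and every window pair (a, b) is scored
#' by the Pearson correlation between the upper triangles of FC(a) and
#' FC(b). The resulting symmetric window-by-window matrix captures how the
#' spatial pattern of connectivity recurs over time.
#'
#' @param series a `subject_series` or matrix.
#' @param window_length window size in frames (default 30, i.e. 60 s at
#'   TR = 2 s).
#' @param window_step step between window starts in frames.
#' @return an `fcd_matrix`: windows x windows matrix with unit diagonal and
#'   `window_length` / `window_step` attributes.
#' @export
fcd_matrix <- function(series, window_length = 30, window_step = 3) {
  m <- as_series_matrix(series)
  abort_if(window_length > ncol(m), "window_length exceeds the series length")
  abort_if(window_step < 1, "window_step must be >= 1")
  starts <- seq(1, ncol(m) - window_length + 1, by = window_step)
  abort_if(length(starts) < 2, "fewer than 2 windows; shorten the window or step")
  ut <- vapply(starts, function(s) {
    upper_tri(cor(t(m[, s:(s + window_length - 1), drop = FALSE])))
  }, numeric(nrow(m) * (nrow(m) - 1) / 2))
  fcd <- cor(ut)
  structure(fcd, window_length = window_length, window_step = window_step,
            class = "fcd_matrix")
}

#' Pooled FCD values for distribution comparison
#'
#' The strict upper triangle of an FCD matrix, the values pooled across
#' subjects when comparing groups.
#'
#' @param fcd an `fcd_matrix` (or square matrix).
#' @return numeric vector of window-pair correlations.
#' @export
fcd_distribution <- function(fcd) {
  upper_tri(if (inherits(fcd, "fcd_matrix")) unclass_matrix(fcd) else fcd)
}

#' Edge metastability
#'
#' The temporal standard deviation (population, divide-by-n) of the
#' collective co-fluctuation amplitude: by default the SD of the RSS trace
#' of the edge time series, indexing how strongly global synchrony
#' fluctuates. `type = "per_edge"` instead averages each edge's own
#' temporal SD.
#'
#' @param edges an `edge_series` (see [edge_time_series()]).
#' @param type `"rss"` (default) or `"per_edge"`.
#' @return nonnegative scalar.
#' @export
edge_metastability <- function(edges, type = c("rss", "per_edge")) {
  type <- match.arg(type)
  m <- if (inherits(edges, "edge_series")) unclass_matrix(edges) else edges
  abort_if(ncol(m) < 2, "need at least 2 frames")
  if (type == "rss") {
    sd_pop(sqrt(colSums(m^2)))
  } else {
    mean(apply(m, 1, sd_pop))
  }
}

#' Constant-Potts quality of a partition on a signed matrix
#'
#' `Q = sum_{i != j} (w_ij - gamma) * delta(c_i, c_j) / sum_{i != j} |w_ij|`.
#' The constant-gamma null keeps the quality well defined on signed weights
#' (negative FC entries are retained, not discarded).
#'
#' @param w symmetric weight matrix (diagonal ignored).
#' @param membership integer community label per node.
#' @param gamma resolution parameter.
#' @return the normalised quality Q.
#' @export
cpm_quality <- function(w, membership, gamma) {
  stopifnot(nrow(w) == length(membership))
  same <- outer(membership, membership, "==")
  diag(same) <- FALSE
  offdiag <- abs(w)
  diag(offdiag) <- 0
  sum((w - gamma)[same]) / sum(offdiag)
}

louvain_cpm <- function(w, gamma, n_restarts = 20, seed = 1) {
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    memb <- .louvain_cpm_cpp(w, gamma, derive_seed(seed, r)) + 1L
    q <- cpm_quality(w, memb, gamma)
    if (q > best_q + 1e-12) {  # ties broken by first-found under seeded order
      best_q <- q
      best <- memb
    }
  }
  list(membership = best, quality = best_q)
}

# greedily merge communities (best CPM quality gain first) until exactly two
# remain -- the agglomerative continuation of Louvain when its optimum has
# more than two communities
merge_to_bipartition <- function(w, membership, gamma) {
  memb <- as.integer(factor(membership))
  wn <- w
  diag(wn) <- 0
  while (length(unique(memb)) > 2) {
    k <- max(memb)
    b <- outer(memb, seq_len(k), "==") * 1
    wc <- crossprod(b, wn %*% b)     # summed weight between communities
    sz <- colSums(b)
    gain <- 2 * (wc - gamma * outer(sz, sz))
    diag(gain) <- -Inf
    pick <- which(gain == max(gain), arr.ind = TRUE)[1, ]
    memb[memb == pick[2]] <- pick[1]
    memb <- as.integer(factor(memb))
  }
  memb
}

# local single-node refinement of a bipartition under the CPM quality;
# keeps both communities nonempty
refine_bipartition <- function(w, membership, gamma) {
  memb <- as.integer(factor(membership))
  wn <- w
  diag(wn) <- 0
  n <- length(memb)
  repeat {
    in2 <- memb == 2
    s2 <- wn %*% in2
    s1 <- wn %*% (!in2)
    n2 <- sum(in2)
    n1 <- n - n2
    # gain of moving node v to the other community
    gain <- ifelse(in2,
                   2 * (s1 - gamma * n1) - 2 * (s2 - wn[cbind(1:n, 1:n)] - gamma * (n2 - 1)),
                   2 * (s2 - gamma * n2) - 2 * (s1 - gamma * (n1 - 1)))
    gain <- as.numeric(gain)
    # forbid emptying a community
    if (n1 == 1) gain[!in2] <- -Inf
    if (n2 == 1) gain[in2] <- -Inf
    v <- which.max(gain)
    if (gain[v] <= 1e-12) break
    memb[v] <- 3L - memb[v]
  }
  memb
}

# best bipartition candidate at one resolution: the Louvain optimum when it
# has two communities, its merged-and-refined continuation when it has
# more, plus refined random bipartition restarts; best quality wins
bipartition_at <- function(w, gamma, n_restarts, seed) {
  fit <- louvain_cpm(w, gamma, n_restarts, seed)
  n_raw <- length(unique(fit$membership))
  if (n_raw < 2) {
    return(list(n_raw = n_raw, membership = NULL, quality = NA_real_))
  }
  memb <- fit$membership
  if (n_raw > 2) memb <- merge_to_bipartition(w, memb, gamma)
  best <- refine_bipartition(w, memb, gamma)
  best_q <- cpm_quality(w, best, gamma)
  n <- nrow(w)
  set.seed(derive_seed(seed, 777))
  for (r in seq_len(n_restarts)) {
    start <- sample(rep_len(1:2, n))
    cand <- refine_bipartition(w, start, gamma)
    q <- cpm_quality(w, cand, gamma)
    if (q > best_q + 1e-12) {
      best <- cand
      best_q <- q
    }
  }
  list(n_raw = n_raw, membership = best, quality = best_q)
}

#' Signed modularity via constant-Potts Louvain bipartition sweep
#'
#' Optimises the constant-Potts quality ([cpm_quality()]) on the full signed
#' FC matrix with a Louvain algorithm at each resolution of a coarse gamma
#' grid, identifies the resolution interval supporting a two-community
#' structure, refines it with a finer sweep, and returns the bipartition
#' with maximal quality. At resolutions where the unconstrained Louvain
#' optimum has more than two communities the agglomeration is continued --
#' communities are greedily merged down to two and polished with
#' single-node moves -- so a bipartition candidate exists wherever the
#' matrix supports any split at all. The default grid extends below zero:
#' on signed or weakly modular matrices (e.g. patient FC with near-silent
#' lesioned regions) the two-community regime can sit at negative
#' resolution, where the constant null rewards merging.
#'
#' @param fc a symmetric `conn_matrix` or matrix (negative entries kept).
#' @param gamma_grid increasing coarse grid of resolutions.
#' @param n_fine number of finer resolutions sampled inside the candidate
#'   interval.
#' @param n_restarts Louvain restarts per resolution (best quality kept).
#' @param seed integer seed for the restart streams.
#' @return a `partition`: list with `membership` (labels 1, 2), `gamma`,
#'   `quality` (normalised Q), `sweep` (tibble: gamma, n_communities --
#'   the unconstrained community count -- and quality of the bipartition
#'   candidate, `NA` where the optimum is a single community).
#' @export
modularity_signed <- function(fc, gamma_grid = seq(-0.3, 1, by = 0.05),
                              n_fine = 10, n_restarts = 20, seed = 1) {
  w <- if (inherits(fc, "conn_matrix")) unclass_matrix(fc) else fc
  abort_if(max(abs(w - t(w))) > 1e-8, "fc must be symmetric")
  abort_if(is.unsorted(gamma_grid, strictly = TRUE), "gamma_grid must be increasing")
  scan <- function(gammas, key) {
    rows <- lapply(seq_along(gammas), function(i) {
      cand <- bipartition_at(w, gammas[i], n_restarts,
                             derive_seed(seed, key + i))
      tibble::tibble(gamma = gammas[i], n_communities = cand$n_raw,
                     quality = cand$quality,
                     membership = list(cand$membership))
    })
    dplyr::bind_rows(rows)
  }
  coarse <- scan(gamma_grid, 0)
  abort_if(all(is.na(coarse$quality)),
           "no resolution produced a bipartition; widen gamma_grid")
  # fine-sample where a two-community structure lives: the interval where
  # the unconstrained optimum has exactly two communities if one exists,
  # plus the transition gap between the single-community regime and the
  # first split (thin bands hide inside that gap)
  fine_g <- numeric(0)
  band <- coarse$gamma[coarse$n_communities == 2]
  if (length(band) && max(band) > min(band)) {
    fine_g <- c(fine_g, seq(min(band), max(band), length.out = n_fine))
  }
  ones <- which(coarse$n_communities < 2)
  many <- which(coarse$n_communities >= 2)
  if (length(ones) && length(many) && max(ones) + 1 == min(many)) {
    gap <- c(coarse$gamma[max(ones)], coarse$gamma[min(many)])
    fine_g <- c(fine_g, seq(gap[1], gap[2],
                            length.out = n_fine + 2)[-c(1, n_fine + 2)])
  }
  fine_g <- setdiff(fine_g, coarse$gamma)
  fine <- if (length(fine_g)) scan(fine_g, 10000) else NULL
  sweep <- dplyr::arrange(dplyr::bind_rows(coarse, fine), .data$gamma)
  cand <- sweep[!is.na(sweep$quality), ]
  best <- cand[which.max(cand$quality), ]
  structure(list(membership = best$membership[[1]], gamma = best$gamma,
                 quality = best$quality,
                 sweep = sweep[, c("gamma", "n_communities", "quality")]),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d communities at gamma = %.3f, Q = %.4f\n",
              length(unique(x$membership)), x$gamma, x$quality))
  invisible(x)
}

#' Functional complexity of a connectivity matrix
#'
#' Measures how far the distribution of pairwise correlations departs from
#' uniform over `[-1, 1]`:
#' `C = 1 - (1/c_m) * sum_mu |p_mu - 1/m|` with `c_m = 2(m-1)/m`, where
#' `p_mu` is the histogram of upper-triangle values over `m` equal bins.
#' C = 0 for a delta distribution (all correlations identical), C = 1 for a
#' perfectly uniform histogram; intermediate regimes between independence
#' and global synchrony score highest.
#'
#' @param fc a `conn_matrix` or square symmetric matrix.
#' @param m number of histogram bins (>= 2; default 20).
#' @return complexity in `[0, 1]`.
#' @export
functional_complexity <- function(fc, m = 20) {
  abort_if(m < 2, "m must be >= 2")
  r <- upper_tri(if (inherits(fc, "conn_matrix")) unclass_matrix(fc) else fc)
  r <- pmin(1, pmax(-1, r))
  # bin index in 1..m over [-1, 1]; right-closed, lowest bin closed
  bin <- pmin(m, pmax(1L, ceiling((r + 1) / (2 / m))))
  p <- tabulate(bin, nbins = m) / length(r)
  c_m <- 2 * (m - 1) / m
  1 - sum(abs(p - 1 / m)) / c_m
}

#' Per-subject dynamical feature table
#'
#' Computes the four preserved dynamical features (mean FCD, edge
#' metastability, signed modularity Q, functional complexity) plus mean
#' irreversibility for each selected series, in whatever space the series
#' lives in. Source and latent values flow through the same code path.
#'
#' @param cohort a `bold_cohort`.
#' @param timepoint series selector (default `"acute"`).
#' @param latent_model optional trained autoencoder; when supplied the
#'   features are computed on the encoded series instead.
#' @param window_length,window_step FCD windowing.
#' @param gamma_grid,n_restarts modularity sweep settings.
#' @param m complexity histogram bins.
#' @param seed integer seed (Louvain restarts).
#' @return tibble: subject_id, group, timepoint, space, fcd_mean,
#'   metastability, modularity_q, complexity, irreversibility.
#' @export
dynamic_features <- function(cohort, timepoint = "acute", latent_model = NULL,
                             window_length = 30, window_step = 3,
                             gamma_grid = seq(-0.3, 1, by = 0.05),
                             n_restarts = 20, m = 20, seed = 1) {
  keys <- cohort_series_keys(cohort, timepoint)
  groups <- setNames(cohort$subjects$group, cohort$subjects$subject_id)
  rows <- lapply(seq_along(keys), function(k) {
    s <- cohort$series[[keys[k]]]
    if (!is.null(latent_model)) s <- encode_series(latent_model, s)
    fc <- fc_matrix(s)
    ed <- edge_time_series(s)
    part <- modularity_signed(fc, gamma_grid = gamma_grid,
                              n_restarts = n_restarts,
                              seed = derive_seed(seed, k))
    sid <- series_tag(s, "subject_id", keys[k])
    tibble::tibble(
      subject_id = sid,
      group = unname(groups[sid]),
      timepoint = series_tag(s, "timepoint", "control"),
      space = series_tag(s, "space", "source"),
      fcd_mean = mean(fcd_distribution(fcd_matrix(s, window_length, window_step))),
      metastability = edge_metastability(ed),
      modularity_q = part$quality,
      complexity = functional_complexity(fc, m = m),
      irreversibility = mean_irreversibility(irreversibility_matrix(s)))
  })
  dplyr::bind_rows(rows)
}
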