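test_that("FCD is a unit-diagonal window correlation matrix", {
  set.seed(1)
  x <- matrix(rnorm(20 * 300), 20, 300)
  fcd <- fcd_matrix(x, window_length = 30, window_step = 10)
  m <- matrix(as.numeric(fcd), nrow(fcd))
  expect_equal(diag(m), rep(1, nrow(m)))
  expect_equal(m, t(m), tolerance = 1e-12)
  expect_true(all(abs(m) <= 1 + 1e-12))
  # stationary white noise: off-diagonal entries near zero on average
  expect_lt(mean(abs(upper_tri(m))), 0.15)
  expect_error(fcd_matrix(x, window_length = 300, window_step = 10),
               "fewer than 2 windows")
})

test_that("windows one period apart of a periodic series have FCD near one", {
  period <- 40
  base <- matrix(rnorm(10 * period), 10, period)
  x <- cbind(base, base, base)  # exact repetition, period = 40
  fcd <- fcd_matrix(x, window_length = 30, window_step = period)
  m <- matrix(as.numeric(fcd), nrow(fcd))
  expect_gt(min(m[cbind(1:2, 2:3)]), 0.99)
})

test_that("FCD distribution extracts the upper triangle", {
  f <- structure(diag(3), window_length = 10, window_step = 2,
                 class = "fcd_matrix")
  expect_length(fcd_distribution(f), 3)
  expect_true(all(fcd_distribution(f) >= -1 & fcd_distribution(f) <= 1))
})

test_that("edge metastability is the population SD of the RSS trace", {
  expect_equal(edge_metastability(matrix(1, 3, 10)), 0)
  # single edge whose |e| alternates 1, 3: RSS trace is 1,3,1,3 -> SD 1
  e <- matrix(rep(c(1, 3), 5), 1, 10)
  expect_equal(edge_metastability(e), 1)
  # invariant to rescaling of the raw signals (z-scoring absorbs scale)
  set.seed(2)
  x <- matrix(rnorm(5 * 50), 5, 50)
  m1 <- edge_metastability(edge_time_series(x))
  m2 <- edge_metastability(edge_time_series(x * 7.3))
  expect_equal(m1, m2, tolerance = 1e-12)
  # per-edge variant is the mean of per-edge SDs
  expect_equal(edge_metastability(e, type = "per_edge"), 1)
})

test_that("constant-Potts quality matches the direct formula", {
  set.seed(3)
  for (k in 1:5) {
    w <- matrix(rnorm(64), 8, 8)
    w <- (w + t(w)) / 2
    diag(w) <- 0
    memb <- sample(1:3, 8, replace = TRUE)
    gamma <- runif(1, -0.2, 0.5)
    direct <- 0
    for (i in 1:8) for (j in 1:8) {
      if (i != j && memb[i] == memb[j]) direct <- direct + (w[i, j] - gamma)
    }
    direct <- direct / sum(abs(w[row(w) != col(w)]))
    expect_equal(cpm_quality(w, memb, gamma), direct, tolerance = 1e-12)
  }
})

test_that("the 4-node anticorrelated pair graph splits as expected", {
  fc4 <- matrix(c(1, .9, -.2, -.2,
                  .9, 1, -.2, -.2,
                  -.2, -.2, 1, .9,
                  -.2, -.2, .9, 1), 4, 4)
  p <- modularity_signed(fc4, gamma_grid = seq(0, 0.5, 0.05), n_restarts = 5)
  expect_equal(length(unique(p$membership)), 2)
  expect_equal(p$membership[1], p$membership[2])
  expect_equal(p$membership[3], p$membership[4])
  expect_true(p$membership[1] != p$membership[3])
  # brute force over all 7 bipartitions at the selected resolution
  oracle <- brute_best_bipartition(fc4, p$gamma)
  expect_equal(p$quality, oracle$quality, tolerance = 1e-12)
})

test_that("modularity is invariant to node relabeling", {
  set.seed(4)
  w <- matrix(rnorm(100), 10, 10)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  p1 <- modularity_signed(w, gamma_grid = seq(-0.5, 1, 0.1), n_restarts = 10,
                          seed = 1)
  perm <- sample(10)
  p2 <- modularity_signed(w[perm, perm], gamma_grid = seq(-0.5, 1, 0.1),
                          n_restarts = 10, seed = 1)
  expect_equal(p2$quality, p1$quality, tolerance = 1e-10)
  # resolutions so low that everything merges leave no split to return
  expect_error(modularity_signed(w, gamma_grid = c(-50, -40), n_restarts = 2),
               "widen gamma_grid")
})

test_that("functional complexity hits the analytic endpoints", {
  # delta distribution: all off-diagonal correlations identical
  delta_fc <- matrix(0.4, 8, 8)
  diag(delta_fc) <- 1
  expect_equal(functional_complexity(delta_fc, 20), 0)
  # exactly uniform histogram: m = 7 bins, 28 edges, 4 values per bin
  m <- 7
  centers <- seq(-1 + 1 / m, 1 - 1 / m, length.out = m)
  vals <- rep(centers, each = 4)
  fc_u <- diag(8)
  fc_u[upper.tri(fc_u)] <- vals
  fc_u <- fc_u + t(fc_u)
  diag(fc_u) <- 1
  expect_equal(functional_complexity(fc_u, m), 1)
  # half the mass in each of two bins at m = 4: C = 1/3
  fc_h <- diag(5)
  fc_h[upper.tri(fc_h)] <- c(rep(-0.9, 5), rep(0.9, 5))
  fc_h <- fc_h + t(fc_h)
  diag(fc_h) <- 1
  expect_equal(functional_complexity(fc_h, 4), 1 / 3, tolerance = 1e-12)
  expect_error(functional_complexity(fc_h, 1), "m must be")
})

test_that("complexity is invariant to node permutation and edge reordering", {
  set.seed(5)
  x <- matrix(rnorm(12 * 80), 12, 80)
  fc <- cor(t(x))
  c0 <- functional_complexity(fc, 10)
  perm <- sample(12)
  expect_equal(functional_complexity(fc[perm, perm], 10), c0, tolerance = 1e-12)
})

test_that("the per-subject feature table computes both spaces via one code path", {
  co <- tiny_cohort()
  small <- co
  small$subjects <- small$subjects[c(1:3, 7:10), ]
  keep <- paste0(small$subjects$subject_id,
                 ifelse(small$subjects$group == "control", "_control", "_2wk"))
  small$series <- small$series[keep]
  ft <- dynamic_features(small, gamma_grid = seq(-0.5, 1, 0.1),
                         n_restarts = 3, window_length = 20, window_step = 10)
  expect_equal(nrow(ft), 7)
  expect_true(all(c("fcd_mean", "metastability", "modularity_q", "complexity",
                    "irreversibility") %in% names(ft)))
  expect_true(all(ft$space == "source"))
  ftl <- dynamic_features(small, latent_model = identity_model(10),
                          gamma_grid = seq(-0.5, 1, 0.1), n_restarts = 3,
                          window_length = 20, window_step = 10)
  expect_true(all(ftl$space == "latent"))
  # identity embedding reproduces the source features exactly
  expect_equal(ftl$complexity, ft$complexity, tolerance = 1e-10)
  expect_equal(ftl$metastability, ft$metastability, tolerance = 1e-10)
})
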