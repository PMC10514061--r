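test_that("edge series are the exact framewise decomposition of Pearson r", {
  # hand case: r = -1 pair
  e <- edge_time_series(rbind(c(1, 2, 3), c(3, 2, 1)))
  expect_equal(as.numeric(e), c(-1.5, 0, -1.5))
  expect_equal(mean(e), -1)
  # identical rows: edge series is z^2 with mean 1
  e2 <- edge_time_series(rbind(c(1, 4, 2, 5), c(1, 4, 2, 5)))
  expect_true(all(e2 >= 0))
  expect_equal(mean(e2), 1)
  # random matrix: row means equal off-diagonal correlations to 1e-12
  set.seed(1)
  x <- matrix(rnorm(200), 5, 40)
  ed <- edge_time_series(x)
  expect_lt(max(abs(rowMeans(ed) - upper_tri(cor(t(x))))), 1e-12)
  idx <- attr(ed, "edge_index")
  expect_equal(nrow(idx), 10)
  expect_true(all(idx$i < idx$j))
})

test_that("RSS amplitude follows the root-sum-square definition", {
  expect_equal(edge_rss(matrix(c(3, -4), 1, 2)), c(3, 4))
  expect_equal(edge_rss(matrix(c(3, 4), 2, 1)), 5)
  expect_equal(edge_rss(matrix(0, 4, 3)), c(0, 0, 0))
  # fast path from z-scores agrees with the explicit edge matrix
  set.seed(2)
  x <- matrix(rnorm(160), 8, 20)
  z <- zscore_rows(x)
  expect_equal(latentdyn:::rss_from_z(unclass(z)),
               edge_rss(edge_time_series(x)), tolerance = 1e-12)
})

test_that("circular-shift null preserves rows as multisets and is seeded", {
  set.seed(4)
  x <- matrix(rnorm(5 * 60), 5, 60)
  n1 <- circshift_null(x, n_iter = 3, seed = 11)
  n2 <- circshift_null(x, n_iter = 3, seed = 11)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(3, 60))
  # every rotated row is a circular permutation of its source row
  z <- unclass(zscore_rows(x))
  rot <- latentdyn:::circshift_rows(z, c(0, 1, 7, 59, 60))
  for (r in 1:5) {
    expect_setequal(rot[r, ], z[r, ])
    expect_true(any(vapply(0:59, function(k) {
      all(rot[r, ] == z[r, c(seq_len(60) - k - 1) %% 60 + 1])
    }, TRUE)))
  }
  expect_equal(rot[1, ], z[1, ])     # zero shift is the identity
  expect_equal(rot[5, ], z[5, ])     # full-length shift wraps to identity
})

test_that("null RSS matches empirical RSS on independent white noise", {
  set.seed(9)
  x <- matrix(rnorm(10 * 1000), 10, 1000)
  z <- unclass(zscore_rows(x))
  emp <- latentdyn:::rss_from_z(z)
  null <- circshift_null(x, n_iter = 200, seed = 1)
  ks <- suppressWarnings(stats::ks.test(emp, as.numeric(null)))
  expect_gt(ks$p.value, 0.01)
})

test_that("peak detection thresholds on the pooled null and z-excludes extremes", {
  rss <- c(1, 2, 3, 2, 1)
  null <- matrix(seq(0.5, 10, length.out = 200), 4, 50)
  ps <- detect_peaks(rss, null, p = 0.1)
  expect_s3_class(ps, "peak_set")
  expect_true(all(ps$peaks %in% 1:5))
  # trace entirely below the null threshold: nothing flagged
  low <- detect_peaks(rep(0.1, 5), null, p = 0.001)
  expect_length(low$peaks, 0)
  expect_error(detect_peaks(rss, null, p = 0.7), "p must lie")
  # a wildly inflated frame is flagged or excluded, never silently absent
  set.seed(5)
  x <- matrix(rnorm(20 * 400), 20, 400)
  x[, 200] <- x[, 200] * 20
  ev <- detect_events(x, n_iter = 200, seed = 2)
  expect_true(200 %in% c(ev$peaks, ev$excluded))
})

test_that("FC from selected frames matches full FC when all frames are used", {
  set.seed(6)
  x <- matrix(rnorm(8 * 100), 8, 100)
  fc_all <- fc_from_frames(x, seq_len(100))
  expect_equal(unclass(fc_all), cor(t(x)), ignore_attr = TRUE)
  expect_error(fc_from_frames(x, 5), "at least 2")
  # two identical frames are a degenerate selection
  x2 <- x
  x2[, 2] <- x2[, 1]
  expect_error(fc_from_frames(x2, c(1, 2)), "degenerate")
})

test_that("event-frame FC correlates strongly with full FC on planted events", {
  co <- tiny_cohort()
  s <- co$series[[1]]
  ev <- detect_events(s, n_iter = 200, p = 0.05, seed = 3)
  frames <- sort(c(ev$peaks, ev$excluded))
  skip_if(length(frames) < 3)
  fc_peaks <- fc_from_frames(s, frames)
  fc_full <- fc_matrix(s)
  expect_gt(cor(upper_tri(unclass(fc_peaks)), upper_tri(unclass(fc_full))), 0.5)
})

test_that("peak agreement counts hits over hits plus misses", {
  mk <- function(peaks, n = 100) {
    structure(list(peaks = peaks, excluded = integer(0), threshold = 1,
                   rss = rep(0, n), n_frames = n, p = 0.001, z_max = 4.5),
              class = "peak_set")
  }
  expect_equal(peak_agreement(mk(c(3, 7, 9)), mk(c(3, 7, 9))), 1)
  expect_equal(peak_agreement(mk(1:3), mk(4:6)), 0)
  expect_equal(peak_agreement(mk(c(10, 20, 30)), mk(c(10, 20, 40))), 0.5)
  expect_equal(peak_agreement(mk(integer(0)), mk(integer(0))), 1)
  expect_error(peak_agreement(mk(1:2, n = 50), mk(1:2, n = 60)), "different lengths")
})

test_that("identity embedding gives near-perfect peak agreement, random gives chance", {
  co <- tiny_cohort()
  model_id <- identity_model(10)
  keys <- head(names(co$series), 4)
  ag_id <- numeric(0)
  ag_rand <- numeric(0)
  set.seed(13)
  for (k in keys) {
    s <- co$series[[k]]
    src <- detect_events(s, n_iter = 150, p = 0.01, seed = 21)
    lat <- detect_events(encode_series(model_id, s), n_iter = 150, p = 0.01,
                         seed = 21)
    ag_id <- c(ag_id, peak_agreement(src, lat))
    rnd <- subject_series(matrix(rnorm(6 * ncol(s)), 6, ncol(s)))
    unrel <- detect_events(rnd, n_iter = 150, p = 0.01, seed = 22)
    ag_rand <- c(ag_rand, peak_agreement(src, unrel))
  }
  expect_true(all(ag_id >= 0.95))
  expect_lt(mean(ag_rand), 0.2)
})
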