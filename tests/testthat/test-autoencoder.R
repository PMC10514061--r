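test_that("training recovers a planted linear subspace and is deterministic", {
  x <- subspace_frames()
  h <- ae_hyper(hidden = c(16, 8), max_epochs = 150, patience = 20,
                learning_rate = 3e-3)
  fit <- train_autoencoder(x, 3, h, seed = 1)
  expect_gte(fit$val_correlation, 0.99)
  fit2 <- train_autoencoder(x, 3, h, seed = 1)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$val_idx, fit2$val_idx)
  # history records both losses per epoch and early stopping restored the best
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(fit$history)))
  expect_equal(fit$val_loss, min(fit$history$val_loss), tolerance = 1e-12)
})

test_that("a linear-capacity bottleneck of full width learns the identity", {
  set.seed(2)
  x <- matrix(rnorm(15 * 1500), 15, 1500)
  fit <- train_autoencoder(
    x, 15, ae_hyper(hidden = integer(0), max_epochs = 100, patience = 100,
                    learning_rate = 0.01, activation = "linear"), seed = 1)
  expect_lt(tail(fit$history$train_loss, 1), 1e-3 * var(as.numeric(x)))
  expect_error(train_autoencoder(x, 16, ae_hyper()), "d <= n_roi")
})

test_that("encoding is framewise, shape-preserving and deterministic", {
  x <- subspace_frames(n = 800)
  fit <- train_autoencoder(x, 3, ae_hyper(hidden = c(8), max_epochs = 10,
                                          patience = 10), seed = 5)
  s <- subject_series(x[, 1:50], subject_id = "a", timepoint = "2wk")
  z <- encode_series(fit, s)
  expect_equal(dim(z), c(3, 50))
  expect_equal(attr(z, "space"), "latent")
  expect_equal(attr(z, "subject_id"), "a")
  # single frame in, single latent frame out
  z1 <- encode_series(fit, x[, 1, drop = FALSE])
  expect_equal(dim(z1), c(3, 1))
  # identical frames map to identical codes
  two <- encode_series(fit, x[, c(2, 2)])
  expect_equal(two[, 1], two[, 2])
  bad <- fit
  bad$trained <- FALSE
  expect_error(encode_series(bad, s), "not trained")
  # encode-decode on training-manifold data generalises
  rec <- reconstruct_frames(fit, x[, 1:200])
  expect_gt(cor(as.numeric(x[, 1:200]), as.numeric(rec)),
            fit$val_correlation - 0.05)
})

test_that("the reconstruction curve rises to the planted dimension then flattens", {
  x <- manifold_frames()
  h <- ae_hyper(hidden = c(32, 16), max_epochs = 80, patience = 10,
                learning_rate = 2e-3)
  rep_ <- reconstruction_curve(x, 2:6, hyper = h, seeds = 3,
                               corr_threshold = 0.9)
  curve <- rep_$curve
  step_34 <- curve$correlation[curve$d == 4] - curve$correlation[curve$d == 3]
  step_45 <- curve$correlation[curve$d == 5] - curve$correlation[curve$d == 4]
  expect_lt(step_45, step_34 / 2)
  # monotone within tolerance across the scanned range
  expect_true(all(diff(curve$correlation) >= -0.02))
  # smallest dimension reaching the threshold is selected
  expect_equal(rep_$selected_d, min(curve$d[curve$correlation >= 0.9]))
  expect_error(reconstruction_curve(x, integer(0)), "empty")
})

test_that("PCA baseline is exact on linear structure and loses to the autoencoder on curved structure", {
  x3 <- subspace_frames(n = 1000)
  pb <- pca_baseline(x3, 3)
  expect_lt(mean((pb$reconstructed - x3)^2), 1e-9)
  pb_full <- pca_baseline(x3, 20)
  expect_equal(pb_full$variance_explained, 1, tolerance = 1e-9)
  xm <- manifold_frames()
  pc4 <- pca_baseline(xm, 4)
  ae4 <- train_autoencoder(xm, 4,
                           ae_hyper(hidden = c(32, 16), max_epochs = 80,
                                    patience = 10, learning_rate = 2e-3),
                           seed = 3)
  expect_gt(ae4$val_correlation, pc4$reconstruction_correlation)
})

test_that("tidiers summarise autoencoder fits", {
  x <- subspace_frames(n = 600)
  fit <- train_autoencoder(x, 2, ae_hyper(hidden = c(8), max_epochs = 5,
                                          patience = 5), seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  g <- glance(fit)
  expect_equal(g$d, 2L)
  expect_gt(g$n_params, 0)
})
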