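test_that("feature tables have the promised geometry", {
  co <- tiny_cohort()
  ft <- build_features(co, "source", "fc", "upper_triangle")
  expect_equal(nrow(ft), 16)
  expect_equal(sum(grepl("^f\\d+$", names(ft))), 10 * 9 / 2)
  model <- identity_model(10)
  fl <- build_features(co, "latent", "irreversibility", "upper_triangle",
                       latent_model = model)
  expect_equal(sum(grepl("^f\\d+$", names(fl))), 45)
  # mean summary of a known matrix
  fm <- build_features(co, "source", "fc", "mean")
  s1 <- co$series[[paste0(ft$subject_id[1], "_",
                          ifelse(ft$group[1] == "control", "control", "2wk"))]]
  expect_equal(fm$f1[1], mean(upper_tri(unclass(fc_matrix(s1)))),
               tolerance = 1e-12)
  expect_error(build_features(co, "latent", "fc"), "latent_model")
  expect_error(build_features(co, subjects = c("ghost1")), "ghost1")
})

test_that("random forests separate a label-equal feature and sit at chance on noise", {
  set.seed(1)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  ft <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                       group = as.character(y),
                       f1 = as.numeric(y == "b"),
                       f2 = rnorm(n))
  class(ft) <- c("feature_table", class(ft))
  rep1 <- rf_classify(ft, y, n_trees = 200, n_repeats = 5, seed = 2)
  expect_gte(attr(rep1, "auc_mean"), 0.99)
  # permuted labels: chance-level AUC
  yp <- factor(sample(as.character(y)))
  ft$f1 <- rnorm(n)
  rep2 <- rf_classify(ft, yp, n_trees = 200, n_repeats = 20, seed = 3)
  expect_gt(attr(rep2, "auc_mean"), 0.3)
  expect_lt(attr(rep2, "auc_mean"), 0.7)
  expect_true(all(rep2$auc >= 0 & rep2$auc <= 1))
  expect_error(rf_classify(ft, factor(rep("a", n))), "two classes")
  g <- glance(rep1)
  expect_named(g, c("auc_mean", "auc_sd", "n_repeats", "n_trees"))
})

test_that("AUC is invariant to strictly monotone transforms of the score", {
  y <- factor(c("a", "a", "a", "b", "b", "b", "a", "b"))
  score <- c(0.1, 0.4, 0.35, 0.8, 0.7, 0.95, 0.2, 0.6)
  a1 <- as.numeric(pROC::auc(y, score, levels = c("a", "b"), direction = "<",
                             quiet = TRUE))
  a2 <- as.numeric(pROC::auc(y, exp(3 * score) - 1, levels = c("a", "b"),
                             direction = "<", quiet = TRUE))
  expect_equal(a1, a2)
})

test_that("Welch comparison matches a textbook evaluation", {
  a <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6, 19.0, 21.7, 21.4)
  b <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5, 24.1)
  res <- group_compare(a, b)
  ref <- t.test(a, b)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-12)
  # hand check of the Welch formula
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 15 + var(b) / 15)
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  set.seed(4)
  sep <- group_compare(rnorm(50), rnorm(50, mean = 5))
  expect_lt(sep$p.value, 1e-10)
  expect_error(group_compare(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("the t-SNE projection is deterministic and separates separable clouds", {
  set.seed(5)
  n <- 30
  x <- rbind(matrix(rnorm(n / 2 * 5), n / 2, 5),
             matrix(rnorm(n / 2 * 5, mean = 8), n / 2, 5))
  ft <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                       group = rep(c("g1", "g2"), each = n / 2))
  ft <- dplyr::bind_cols(ft, tibble::as_tibble(
    stats::setNames(as.data.frame(x), paste0("f", 1:5))))
  class(ft) <- c("feature_table", class(ft))
  p1 <- tsne_project(ft, seed = 7)
  p2 <- tsne_project(ft, seed = 7)
  expect_identical(p1, p2)
  expect_equal(dim(as.matrix(p1[, c("tsne1", "tsne2")])), c(n, 2))
  # silhouette of the true labels on the projection
  xy <- as.matrix(p1[, c("tsne1", "tsne2")])
  d <- as.matrix(dist(xy))
  sil <- vapply(1:n, function(i) {
    own <- ft$group[i] == ft$group
    ai <- mean(d[i, own & seq_len(n) != i])
    bi <- mean(d[i, !own])
    (bi - ai) / max(ai, bi)
  }, 1)
  expect_gt(mean(sil), 0.5)
})

test_that("behavior correlations recover a planted metric-domain link", {
  co <- tiny_cohort()
  bc <- behavior_correlations(co, identity_model(10), target = "acute")
  expect_equal(nrow(bc), 4 * 9)
  expect_setequal(unique(bc$metric),
                  c("fc_source", "irrev_source", "fc_latent", "irrev_latent"))
  # each domain's best flag marks the largest |r| among the four metrics
  for (dom in unique(bc$domain)) {
    sub <- bc[bc$domain == dom & !is.na(bc$r), ]
    expect_equal(sub$metric[sub$best][1],
                 sub$metric[which.max(abs(sub$r))])
  }
  # identity-embedding parity: latent metrics equal source metrics exactly,
  # so their correlations coincide
  expect_equal(bc$r[bc$metric == "fc_latent"], bc$r[bc$metric == "fc_source"],
               tolerance = 1e-8)
})
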