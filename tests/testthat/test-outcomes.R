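test_that("FC distance is the Frobenius norm with metric properties", {
  a <- diag(4)
  expect_equal(fc_distance(a, a), 0)
  b <- a
  b[1, 2] <- b[2, 1] <- 0.5
  expect_equal(fc_distance(a, b), sqrt(0.5), tolerance = 1e-12)
  set.seed(1)
  for (k in 1:5) {
    x <- matrix(rnorm(9), 3, 3)
    y <- matrix(rnorm(9), 3, 3)
    z <- matrix(rnorm(9), 3, 3)
    expect_lte(fc_distance(x, z), fc_distance(x, y) + fc_distance(y, z) + 1e-12)
  }
  expect_error(fc_distance(diag(3), diag(4)), "shape")
})

test_that("the control reference FC is the elementwise group mean", {
  co <- tiny_cohort()
  one <- co
  one$subjects <- one$subjects[1, ]
  expect_equal(unclass(reference_fc(one)),
               unclass(fc_matrix(co$series[["ctrl001_control"]])),
               ignore_attr = TRUE)
  two <- co
  two$subjects <- two$subjects[1:2, ]
  mid <- (unclass(fc_matrix(co$series[["ctrl001_control"]])) +
            unclass(fc_matrix(co$series[["ctrl002_control"]]))) / 2
  expect_equal(unclass(reference_fc(two)), mid, ignore_attr = TRUE)
  none <- co
  none$subjects <- co$subjects[co$subjects$group == "patient", ]
  expect_error(reference_fc(none), "no controls")
})

test_that("SC-FC coupling is the masked upper-triangle correlation", {
  sc <- matrix(0, 4, 4)
  sc[upper.tri(sc)] <- c(1, 2, 0, 3, 4, 5)
  sc <- sc + t(sc)
  fc <- sc * 0.31
  expect_equal(sc_fc_coupling(fc, sc), 1)
  expect_equal(sc_fc_coupling(-fc, sc), -1)
  expect_error(sc_fc_coupling(fc, matrix(0, 4, 4)), "degenerate")
})

test_that("behavioral recovery is the relative change from the 2-week baseline", {
  expect_equal(behavioral_recovery(10, 15), 0.5)
  expect_equal(behavioral_recovery(7, 7), 0)
  expect_equal(behavioral_recovery(-2, -1), -0.5)
  expect_true(is.na(behavioral_recovery(0, 3)))
  expect_equal(behavioral_recovery(c(10, 0, -2), c(15, 1, -1)),
               c(0.5, NA, -0.5))
})

test_that("domain recovery counting supports both stated rules", {
  beh <- tidyr::expand_grid(subject_id = c("p1", "p2"),
                            timepoint = c("2wk", "1yr"),
                            domain = sprintf("d%d", 1:9))
  # p1: all domains normalise; p2: none do
  beh$score <- ifelse(beh$subject_id == "p1" & beh$timepoint == "1yr", -0.2,
                      -2.5)
  dr <- domains_recovered(beh)
  expect_equal(dr$domains_recovered[dr$subject_id == "p1"], 9)
  expect_equal(dr$domains_recovered[dr$subject_id == "p2"], 0)
  # improvement rule: p1 improved everywhere, p2 not at all
  dri <- domains_recovered(beh, rule = "improvement")
  expect_equal(dri$domains_recovered[dri$subject_id == "p1"], 9)
  expect_equal(dri$domains_recovered[dri$subject_id == "p2"], 0)
  # unchanged scores count as zero under the improvement rule
  beh0 <- beh
  beh0$score <- -1.5
  dri0 <- domains_recovered(beh0, rule = "improvement")
  expect_true(all(dri0$domains_recovered == 0))
})

test_that("median split balances labels and applies the documented tie rule", {
  s1 <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s1), c("low", "low", "high", "high"))
  s2 <- median_split(c(1, 2, 2, 3))
  expect_equal(table(s2)[["low"]], 2)
  expect_equal(table(s2)[["high"]], 2)
  expect_equal(as.character(s2), c("low", "low", "high", "high"))
  s3 <- median_split(c(1, 1, 2, 2, 2, 2))
  expect_equal(unname(abs(diff(table(s3)))), 0)
  expect_error(median_split(c(1, 2, 3)), "at least 4")
  expect_error(median_split(rep(2, 6)), "identical")
  # balance within one for odd lengths
  s4 <- median_split(c(5, 1, 4, 2, 3))
  expect_lte(abs(diff(table(s4))), 1)
})

test_that("kappa agreement is 1 for identical labels and near 0 for independent ones", {
  a <- factor(rep(c("low", "high"), 10))
  expect_equal(kappa_agreement(a, a)$kappa, 1)
  set.seed(2)
  b <- factor(sample(c("low", "high"), 20, replace = TRUE))
  expect_lt(abs(kappa_agreement(a, b)$kappa), 0.6)
})

test_that("the outcome table carries distances, couplings, counts and balanced labels", {
  co <- tiny_cohort()
  out <- outcome_table(co)
  expect_equal(nrow(out), 10)
  expect_true(all(out$fc_distance_2wk >= 0))
  expect_true(all(abs(out$sc_fc_2wk) <= 1))
  expect_true(all(out$domains_recovered %in% 0:9))
  for (lab in c("label_behavior", "label_fcdist", "label_scfc")) {
    expect_lte(abs(diff(table(out[[lab]]))), 1)
  }
})
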