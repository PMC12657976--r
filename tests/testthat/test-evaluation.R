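test_that("total-cellularity and total-volume changes follow their definitions", {
  d <- c(3, 3, 1)
  a <- array(100, d)
  expect_equal(pct_delta_ttc(a, 2 * a), 100)
  expect_equal(pct_delta_ttc(a, a), 0)
  expect_equal(pct_delta_ttc(a, 0.75 * a), -25)
  expect_error(pct_delta_ttc(array(0, d), a), "zero")

  th <- 100
  x <- array(c(20, 30, rep(0, 7)), d)   # threshold 0.25*theta = 25
  expect_equal(sum(x >= 0.25 * th), 1)
  expect_equal(pct_delta_ttv(x, x, th), 0)
  y <- array(c(30, 30, 30, 30, rep(0, 5)), d)
  y2 <- array(c(30, 30, rep(0, 7)), d)
  expect_equal(pct_delta_ttv(y, y2, th), -50)
  expect_error(pct_delta_ttv(array(0, d), y, th), "tumor-bearing")
  expect_error(pct_delta_ttv(y, y2, th, threshold_fraction = 1.5), "0, 1")
})

test_that("voxelwise fractional-change MSE matches a double-loop computation", {
  d <- c(4, 3, 2)
  roi <- array(TRUE, d)
  set.seed(9)
  da <- array(runif(prod(d), 10, 100), d)
  db <- array(runif(prod(d), 10, 100), d)
  expect_equal(mse_pct_delta_tc(da, db, da, db, roi), 0)

  # constant offset in the fractional change: MSE = offset^2
  mb <- db + 0.1 * pmax(da, 1)
  expect_equal(mse_pct_delta_tc(da, mb, da, db, roi), 0.01, tolerance = 1e-12)

  # random fields against the naive loop (including empty-at-V1 guard voxels)
  ma <- da; mb2 <- array(runif(prod(d), 0, 120), d)
  da2 <- da; da2[1, 1, 1] <- 0
  acc <- 0
  for (i in which(roi)) {
    fm <- (mb2[i] - ma[i]) / max(ma[i], 1)
    fd <- (db[i] - da2[i]) / max(da2[i], 1)
    acc <- acc + (fm - fd)^2
  }
  expect_equal(mse_pct_delta_tc(ma, mb2, da2, db, roi), acc / sum(roi),
               tolerance = 1e-12)
  expect_error(mse_pct_delta_tc(da, db, da, db, array(FALSE, d)), "empty")
})

test_that("KS and rank-sum wrappers agree with exhaustive statistics", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(2.0, 2.9, 6.1, 0.4, 3.3, 4.8)
  ks <- ks_two_sample(x, y)
  expect_equal(ks$statistic, oracle_ks_stat(x, y), tolerance = 1e-12)
  same <- ks_two_sample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)

  # rank-sum: identity is non-significant, full separation is extreme
  expect_gt(wilcoxon_rank_sum(x, x), 0.9)
  expect_lt(wilcoxon_rank_sum(1:10, 21:30), 1e-3)
  # W statistic equals the brute-force U count
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))$statistic
  expect_equal(unname(w), oracle_u_stat(x, y))
})

test_that("AUC equals Mann-Whitney pair counting on many small inputs", {
  r <- roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # swapping one concordant pair of the perfect ordering drops one of the
  # four positive/negative comparisons: AUC = 3/4
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)

  set.seed(4)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(1:8, n, TRUE)    # ties included
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  # label-independent scores give chance-level AUC at large n
  set.seed(11)
  sc <- rnorm(2000); lb <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(sc, lb)$auc - 0.5), 0.05)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both")
})

test_that("DeLong comparisons match the placement-value formula", {
  expect_equal(delong_test(c(1, 2, 3, 4), c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  set.seed(21)
  n <- 40
  lb <- rep(0:1, each = n / 2)
  s1 <- rnorm(n, mean = lb)
  s2 <- 0.5 * s1 + rnorm(n, mean = 0.7 * lb)
  expect_equal(delong_test(s1, s2, lb), oracle_delong_p(s1, s2, lb),
               tolerance = 1e-6)
})

test_that("optimal-H selection is parsimonious and monotone-safe", {
  set.seed(2)
  base <- data.frame(ttc = runif(12, 5, 10), ttv = runif(12, 5, 10),
                     msetc = runif(12, 0.05, 0.2))
  # identical distributions at every H: the smallest H wins
  tabs <- list(`2` = base, `3` = base, `4` = base)
  sel <- select_optimal_H(tabs)
  expect_equal(sel$H_opt, 2)
  expect_true(sel$qualified)
  # appending another H with the same distribution never changes the choice
  tabs5 <- c(tabs, list(`5` = base))
  expect_equal(select_optimal_H(tabs5)$H_opt, 2)

  # a large improvement from H=2 to H=3 moves the choice to 3
  worse <- base; worse[] <- lapply(base, function(v) v + 100)
  tabs2 <- list(`2` = worse, `3` = base, `4` = base)
  expect_equal(select_optimal_H(tabs2)$H_opt, 3)

  # when every larger H keeps improving, no H qualifies
  tabs3 <- list(`2` = worse, `3` = base,
                `4` = data.frame(ttc = base$ttc - 100, ttv = base$ttv - 100,
                                 msetc = base$msetc - 100))
  sel3 <- select_optimal_H(tabs3)
  expect_equal(sel3$H_opt, 4)
  expect_false(sel3$qualified)

  # degenerate single-patient tables cannot be compared
  one <- lapply(tabs, function(t) t[1, , drop = FALSE])
  expect_error(select_optimal_H(one), "two patients")
})
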