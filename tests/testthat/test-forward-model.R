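test_that("therapy factor is causal and sums exponential decays", {
  s <- therapy_schedule(drugs = "a", beta = 0.5, dose_days = list(c(0, 21)))
  expect_equal(therapy_factor(s, 21), exp(-10.5) + 1, tolerance = 1e-12)
  s2 <- therapy_schedule(drugs = "a", beta = 0.5, dose_days = list(5))
  expect_equal(therapy_factor(s2, 4.9), 0)   # future dose contributes nothing
  expect_equal(therapy_factor(s2, 5), 1)     # exp(0) at the dose time
  # two drugs superpose
  s3 <- therapy_schedule(drugs = c("a", "b"), beta = c(1, 2),
                         dose_days = list(0, 0))
  expect_equal(therapy_factor(s3, 2), exp(-2) + exp(-4), tolerance = 1e-12)
  expect_error(therapy_schedule(beta = c(-1, 2)), "positive")
})

test_that("single-voxel dynamics match the logistic and drug-decay solutions", {
  theta <- 2e5
  init <- array(theta / 10, c(1, 1, 1))
  # logistic growth: N(t) = theta / (1 + 9 exp(-k t)) for N0 = theta/10
  sim <- simulate_tumor(single_voxel_params(k = 0.1, alpha = 0), init,
                        c(0, 30), dt = 0.01)
  expect_equal(sim$snapshots[[1]][1], theta / (1 + 9 * exp(-3)),
               tolerance = 1e-3)
  # drug-only decay: N(t) = N0 exp(-(alpha/beta)(1 - exp(-beta t)))
  sch <- therapy_schedule(drugs = "d", beta = 1, dose_days = list(0))
  sim2 <- simulate_tumor(single_voxel_params(k = 0, alpha = 0.3, schedule = sch),
                         init, c(0, 10), dt = 0.01)
  expect_equal(sim2$snapshots[[1]][1],
               theta / 10 * exp(-0.3 * (1 - exp(-10))), tolerance = 1e-3)
})

test_that("pure diffusion conserves total cell number under no-flux boundaries", {
  d <- c(10, 10, 6)
  roi <- array(TRUE, d)
  N0 <- array(0, d); N0[5, 5, 3] <- 1e5
  ps <- model_parameter_set("global", k = 0, alpha = 0, D0 = 0.3, theta = 2e5,
                            C = array(0, d),
                            schedule = therapy_schedule(
                              dose_days = rep(list(numeric(0)), 2)),
                            roi = roi, mask = roi)
  sim <- simulate_tumor(ps, N0, c(0, 20), dt = 0.05)
  expect_lt(abs(sum(sim$snapshots[[1]]) - 1e5) / 1e5, 1e-6)
  expect_true(all(sim$snapshots[[1]] >= 0))
})

test_that("proliferation parameterizations expand correctly", {
  d <- c(4, 4, 2)
  roi <- array(FALSE, d); roi[2:3, 2:3, ] <- TRUE
  hab <- array(0L, d); hab[2:3, 2:3, ] <- rep(1:2, each = 2)
  sched <- therapy_schedule()
  base <- function(scheme, k, hm = NULL)
    model_parameter_set(scheme, k = k, alpha = 0, D0 = 0, theta = 1e5,
                        C = array(1, d), schedule = sched, roi = roi,
                        mask = array(TRUE, d), habitat_map = hm)
  kg <- expand_k(base("global", 0.05))
  expect_true(all(kg[roi] == 0.05) && all(kg[!roi] == 0))
  kh <- expand_k(base("habitat", c(0.01, 0.09), hab))
  expect_equal(sort(unique(kh[roi])), c(0.01, 0.09))
  kv <- seq_len(sum(roi)) * 1e-3
  kl <- expand_k(base("local", kv))
  expect_equal(kl[roi], kv)
  expect_error(base("habitat", c(0.01), hab), "k value")
  expect_error(base("habitat", c(0.01, 0.02)), "habitat_map")
  expect_error(base("local", c(0.01)), "k value")
})

test_that("stronger therapy never increases the tumor burden", {
  cfg <- tiny_config()
  base <- generate_cellularity_field(cfg, seed = 8)
  d <- cfg$grid_shape
  sched <- therapy_schedule()
  mk <- function(alpha) model_parameter_set(
    "global", k = 0.05, alpha = alpha, D0 = 0.05, theta = base$theta,
    C = array(0.8, d), schedule = sched, roi = base$roi, mask = array(TRUE, d))
  out <- lapply(c(0, 0.3, 1), function(a)
    simulate_tumor(mk(a), base$cellularity, c(0, 42), dt = 0.1,
                   output_times = c(21, 42)))
  tot <- sapply(out, function(s) vapply(s$snapshots, sum, numeric(1)))
  expect_true(all(diff(t(tot)) <= 0))  # alpha up -> burden down at every time
})

test_that("halving the time step changes the predicted totals by under 1%", {
  cfg <- phantom_config(seed = 55L)   # default-size phantom
  vp <- generate_virtual_patient(cfg)
  gt <- vp$ground_truth
  ps <- model_parameter_set(
    "habitat", k = gt$k_by_region, alpha = gt$alpha, D0 = cfg$D0,
    theta = vp$theta, C = gt$C, schedule = vp$schedule, roi = vp$roi,
    mechanics = vp$mechanics, habitat_map = gt$region_labels)
  v3 <- function(dt) sum(simulate_tumor(ps, gt$cellularity[[1]], c(0, 84),
                                        dt = dt)$snapshots[[1]])
  expect_lt(abs(v3(0.025) - v3(0.05)) / v3(0.05), 0.01)
})

test_that("the stability bound reduces the step and instability is reported", {
  d <- c(6, 6, 4)
  roi <- array(TRUE, d)
  ps <- model_parameter_set("global", k = 0, alpha = 0, D0 = 5, theta = 1e5,
                            C = array(0, d),
                            schedule = therapy_schedule(
                              dose_days = rep(list(numeric(0)), 2)),
                            roi = roi, mask = roi)
  sim <- simulate_tumor(ps, array(10, d), c(0, 1), dt = 0.5)
  expect_lt(sim$diagnostics$dt, 0.5)
  expect_lte(sim$diagnostics$dt, 0.9 * 1 / (6 * 5) + 1e-12)
  expect_error(simulate_tumor(ps, array(2e5 + 1, d), c(0, 1)), "theta")
})
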