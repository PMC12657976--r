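test_that("two-point ADC fit matches the closed form and flags bad voxels", {
  d <- c(2, 2, 1)
  s100 <- array(1000, d)
  s800 <- array(1000 * exp(-0.7), d)
  adc <- fit_adc(s100, s800)
  expect_equal(as.vector(adc), rep(1.0e-3, 4), tolerance = 1e-12)

  # equal signals give zero ADC; inverted signals give a flagged negative
  adc0 <- fit_adc(s100, s100)
  expect_true(all(adc0 == 0))
  adcn <- fit_adc(s800, s100)
  expect_true(all(adcn < 0))
  expect_true(all(attr(adcn, "negative")))

  # non-positive signal is invalid (NA), and two equal b-values error
  sbad <- s100; sbad[1, 1, 1] <- 0
  adcb <- fit_adc(sbad, s800)
  expect_true(is.na(adcb[1, 1, 1]))
  expect_true(attr(adcb, "invalid")[1, 1, 1])
  expect_error(fit_adc(s100, s800, b_values = c(100, 100)), "distinct")
})

test_that("carrying capacity follows sphere-packing geometry", {
  th <- carrying_capacity(1)
  expect_equal(th, 0.7405 / ((4 / 3) * pi * 1e-6), tolerance = 1e-12)
  expect_equal(th, 1.768e5, tolerance = 2e-4)
  expect_equal(carrying_capacity(2), 2 * th, tolerance = 1e-12)
  expect_equal(carrying_capacity(1, packing = 0), 0)
  expect_error(carrying_capacity(-1), "positive")
})

test_that("cellularity mapping hits its anchor points and validates adc_min", {
  th <- 1e5
  adc <- array(c(0.5e-3, ADC_WATER, (ADC_WATER + 0.5e-3) / 2, 2e-3), c(4, 1, 1))
  n <- cellularity_map(adc, adc_min = 0.5e-3, theta = th)
  expect_equal(n[1, 1, 1], th)
  expect_equal(n[2, 1, 1], 0)
  expect_equal(n[3, 1, 1], th / 2)
  expect_error(cellularity_map(adc, adc_min = 4e-3, theta = th), "adc_min")
})

test_that("noiseless DWI synthesis and feature inversion is the identity", {
  th <- carrying_capacity(1.5)
  set.seed(42)
  cell <- array(runif(60, 0, th), c(5, 4, 3))
  dwi <- synthesize_dwi(cell, th, adc_min = 0.5e-3, noise_sd = 0)
  adc <- fit_adc(dwi$s_low, dwi$s_high)
  back <- cellularity_map(adc, adc_min = 0.5e-3, theta = th)
  expect_lt(max(abs(back - cell)) / th, 1e-10)
})

test_that("DCE resampling is linear interpolation with coverage checks", {
  d <- c(2, 2, 1)
  # identity on the target grid
  tt <- seq(0, 360, by = 10)
  sig <- array(rep(tt, each = prod(d)), c(d, length(tt)))
  rs <- resample_dce(sig, tt)
  expect_equal(rs$signal, sig)
  # a linear ramp sampled at 11.1 s resamples exactly (linear interp of linear)
  t2 <- seq(0, 400, by = 11.1)
  sig2 <- array(rep(3 * t2 + 7, each = prod(d)), c(d, length(t2)))
  rs2 <- resample_dce(sig2, t2)
  expect_equal(as.vector(rs2$signal[1, 1, 1, ]), 3 * tt + 7, tolerance = 1e-10)
  # curvature-bounded error for a smooth nonlinear curve: |err| <= h^2/8 max|f''|
  f <- function(t) sin(t / 60)
  sig3 <- array(rep(f(t2), each = prod(d)), c(d, length(t2)))
  rs3 <- resample_dce(sig3, t2)
  bound <- 11.1^2 / 8 * (1 / 60^2)
  expect_lt(max(abs(as.vector(rs3$signal[1, 1, 1, ]) - f(tt))), bound * 1.01)
  # insufficient coverage errors
  expect_error(resample_dce(sig2[, , , 1:10, drop = FALSE], t2[1:10]), "s required")
})

test_that("DCE normalization maps to [0,1], is affine-invariant, guards flat curves", {
  d <- c(2, 2, 1)
  tt <- seq(0, 360, by = 10)
  set.seed(7)
  sig <- array(runif(prod(d) * length(tt)), c(d, length(tt)))
  nz <- normalize_dce(sig)
  mat <- matrix(nz$signal, nrow = prod(d))
  expect_equal(unname(apply(mat, 1, min)), rep(0, prod(d)))
  expect_equal(unname(apply(mat, 1, max)), rep(1, prod(d)))
  nz2 <- normalize_dce(3.7 * sig + 11)
  expect_equal(nz2$signal, nz$signal, tolerance = 1e-12)
  flat <- array(5, c(d, length(tt)))
  nzf <- normalize_dce(flat)
  expect_true(all(nzf$signal == 0))
  expect_true(all(nzf$flat))
})

test_that("MSI and PEI match their closed forms on canonical curves", {
  d <- c(2, 2, 1); nt <- 37
  ramp <- array(rep(seq(0, 1, length.out = nt), each = prod(d)), c(d, nt))
  expect_equal(max(abs(compute_msi(ramp) - 1 / 360)), 0, tolerance = 1e-12)
  expect_equal(as.vector(compute_pei(ramp)), rep(185, prod(d)), tolerance = 1e-10)
  ones <- array(1, c(d, nt))
  expect_equal(as.vector(compute_pei(ones)), rep(370, prod(d)))
  expect_equal(as.vector(compute_pei(ones * 0)), rep(0, prod(d)))
  # a unit step between consecutive frames gives MSI = 1/dtau
  step <- array(rep(c(rep(0, 10), rep(1, nt - 10)), each = prod(d)), c(d, nt))
  expect_equal(as.vector(compute_msi(step)), rep(0.1, prod(d)))
  # strictly decreasing normalized curve gives a negative MSI
  dec <- array(rep(seq(1, 0, length.out = nt), each = prod(d)), c(d, nt))
  expect_true(all(compute_msi(dec) < 0))
  expect_error(compute_msi(ones[, , , 1, drop = FALSE]), "two frames")
})

test_that("MSI and PEI are invariant to affine raw-signal rescaling", {
  cfg <- tiny_config()
  base <- generate_cellularity_field(cfg, seed = 5)
  dce <- synthesize_dce(base$region_labels, cfg$region_archetypes,
                        cfg$background_dce, noise_sd = 1, seed = 2)
  n1 <- normalize_dce(dce$signal)$signal
  n2 <- normalize_dce(2.5 * dce$signal - 40)$signal
  expect_equal(compute_msi(n1), compute_msi(n2), tolerance = 1e-10)
  expect_equal(compute_pei(n1), compute_pei(n2), tolerance = 1e-10)
  # SER is invariant under multiplicative rescaling of the raw signal
  tt <- dce$frame_times
  expect_equal(compute_ser(dce$signal, tt)$ser,
               compute_ser(3 * dce$signal, tt)$ser, tolerance = 1e-10)
})

test_that("SER reproduces the frame-mean arithmetic and guards", {
  tt <- seq(0, 360, by = 10)
  sig <- ramp_dce()
  ser <- compute_ser(sig, tt)
  # linear ramp 100->200: S0 = 925/9, S1 = 1200/9, S2 = 1775/9 -> SER = 11/34
  expect_equal(ser$ser[1, 1, 1], 11 / 34, tolerance = 1e-12)
  expect_false(any(ser$flagged))
  flat <- array(100, dim(sig))
  serf <- compute_ser(flat, tt)
  expect_true(all(serf$flagged))
  expect_true(all(serf$ser == 0))
  expect_error(compute_ser(sig[, , , 1:30, drop = FALSE], tt[1:30]), "missing")
})

test_that("drug concentration is the max-normalized PEI", {
  d <- c(3, 2, 1); nt <- 37
  mask <- array(TRUE, d)
  uni <- array(rep(seq(0, 1, length.out = nt), each = prod(d)), c(d, nt))
  expect_equal(as.vector(drug_concentration(uni, mask)), rep(1, prod(d)))
  half <- uni; half[1, 1, 1, ] <- uni[1, 1, 1, ] / 2
  expect_equal(drug_concentration(half, mask)[1, 1, 1], 0.5, tolerance = 1e-12)
  expect_error(drug_concentration(uni * 0, mask), "zero")
})
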