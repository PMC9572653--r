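test_that("fitters recover noiseless monoexponential parameters", {
  irf <- irf_spec(167)
  h <- noiseless_histogram(decay_model(1, 2), irf)
  f_n <- fit_nlsm(h, irf, 1)
  f_v <- fit_vpm(h, irf, 1)
  expect_true(f_n$converged)
  expect_lt(abs(f_n$tau - 2) / 2, 1e-3)
  expect_lt(abs(f_v$tau - 2) / 2, 1e-3)
  expect_lt(abs(f_n$tau_a - f_v$tau_a) / f_n$tau_a, 0.01)
})

test_that("fitters recover noiseless biexponential parameters when identifiable", {
  irf <- irf_spec(167)
  m <- decay_model(c(0.4, 0.6), c(0.8, 3))  # tau2/tau1 well separated
  h <- noiseless_histogram(m, irf)
  for (f in list(fit_nlsm(h, irf, 2), fit_vpm(h, irf, 2))) {
    expect_lt(max(abs(f$tau - c(0.8, 3)) / c(0.8, 3)), 1e-3)
    expect_lt(max(abs(f$alpha - c(0.4, 0.6))), 1e-3)
    expect_lt(abs(f$tau_a - 2.12) / 2.12, 1e-3)
    expect_equal(sum(f$alpha), 1)
  }
})

test_that("biexponential components are canonically ordered and swap-invariant", {
  irf <- irf_spec(167)
  h <- noiseless_histogram(decay_model(c(0.3, 0.7), c(0.6, 2.5)), irf)
  f1 <- fit_nlsm(h, irf, 2, init = list(tau = c(0.5, 2.8)))
  f2 <- fit_nlsm(h, irf, 2, init = list(tau = c(2.8, 0.5)))
  expect_lt(f1$tau[1], f1$tau[2])
  expect_lt(f2$tau[1], f2$tau[2])
  expect_equal(f1$tau_a, f2$tau_a, tolerance = 1e-3)
})

test_that("equal-lifetime biexponential fit degenerates to the mono fit", {
  irf <- irf_spec(167)
  h <- noiseless_histogram(decay_model(1, 1.7), irf)
  f1 <- fit_vpm(h, irf, 1)
  f2 <- fit_vpm(h, irf, 2)
  expect_equal(f2$tau_a, f1$tau_a, tolerance = 0.02)
  fm <- asNamespace("flimmixer")
  D <- cbind(1:5, 1:5)
  expect_warning(fm$solve_amplitudes(D, c(1, 2, 3, 4, 5) * 1.0),
                 "near-singular")
})

test_that("center of mass estimates the mean decay time", {
  ax <- time_axis()
  h <- noiseless_histogram(decay_model(1, 1), irf_spec(0, t0 = 0), ax)
  expect_equal(fit_cmm(h, 0), 1, tolerance = 0.01)
  # window truncation biases long lifetimes downward by the truncated mean
  ax5 <- time_axis(128L, 0.039)  # ~5 tau window for tau = 1
  h5 <- noiseless_histogram(decay_model(1, 1), irf_spec(0, t0 = 0), ax5)
  W <- ax5$window
  truncated_mean <- 1 - W * exp(-W) / (1 - exp(-W))
  expect_lt(fit_cmm(h5, 0), 1)
  expect_equal(fit_cmm(h5, 0), truncated_mean, tolerance = 0.01)
  # intensity weighting exceeds amplitude weighting for mixed decays
  m <- decay_model(c(0.5, 0.5), c(0.5, 3))
  hb <- noiseless_histogram(m, irf_spec(0, t0 = 0))
  expect_gt(fit_cmm(hb, 0), amplitude_weighted_lifetime(m))
})

test_that("fit input validation rejects unusable histograms", {
  ax <- time_axis(32L, 0.3)
  empty <- decay_histogram(c(1L, rep(0L, 31L)), ax)
  expect_error(fit_nlsm(empty, irf_spec(167), 1), "empty")
  h <- noiseless_histogram(decay_model(1, 2), irf_spec(167))
  expect_error(fit_nlsm(h, irf_spec(167), 3), "must be 1 or 2")
})
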