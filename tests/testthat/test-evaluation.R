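test_that("relative bias follows the mean-estimator definition", {
  expect_equal(relative_bias(rep(0.98, 5), 1), 0.02)
  expect_equal(relative_bias(c(2, 2, 2), 2), 0)
  expect_equal(relative_bias(c(0.9, 1.1), 1), 0)  # symmetric errors cancel
  expect_error(relative_bias(c(1, 2), 0), "positive")
})

test_that("std around truth matches its printed formula", {
  expect_equal(std_around_truth(c(1, 1, 1), 1), 0)
  expect_equal(std_around_truth(c(0.9, 1.1), 1), sqrt(0.02 / 1))
  expect_error(std_around_truth(1, 1), "at least two")
  # brute-force decomposition: equals the sample sd iff the mean hits truth
  set.seed(31)
  for (i in 1:20) {
    est <- rnorm(25, mean = runif(1, 0.5, 4), sd = 0.3)
    truth <- runif(1, 0.5, 4)
    brute <- sqrt(sum((est - truth)^2) / (length(est) - 1))
    expect_equal(std_around_truth(est, truth), brute)
    expect_gte(std_around_truth(est, truth) + 1e-12, abs(mean(est) - truth))
  }
  centered <- c(0.8, 1.2, 0.9, 1.1)  # mean exactly at truth
  expect_equal(std_around_truth(centered, 1), sd(centered))
})

test_that("mono benchmark tabulates deterministically and an ideal estimator is unbiased", {
  tb1 <- run_mono_benchmark("cmm", lifetimes = 1, n_replicates = 5L,
                            snr_bins = list(c(30, 34)), seed = 3)
  tb2 <- run_mono_benchmark("cmm", lifetimes = 1, n_replicates = 5L,
                            snr_bins = list(c(30, 34)), seed = 3)
  expect_identical(tb1, tb2)
  expect_named(tb1, c("method", "tau_true", "snr_lo", "snr_hi",
                      "mean_estimate", "bias", "std", "n"))
  # the truth itself has zero bias in every cell by construction
  expect_equal(relative_bias(rep(tb1$tau_true[1], 10), tb1$tau_true[1]), 0)
})

test_that("biexponential benchmark reduces to mono at alpha = 1", {
  tb <- run_bi_benchmark("cmm", alpha_values = 1, snr_points_db = 38,
                         n_per_cell = 20L, seed = 7)
  # with alpha = 1 the truth is tau1 ~ U[0.5, 1.5]; CMM sees a mono decay
  expect_true(all(tb$mean_truth > 0.5 & tb$mean_truth < 1.5))
  expect_lt(tb$bias, 0.15)
})

test_that("SSIM is 1 on identical maps and penalizes offsets", {
  set.seed(7)
  a <- matrix(runif(64 * 64), 64, 64)
  expect_equal(ssim(a, a), 1, tolerance = 1e-9)
  expect_lt(ssim(a, a + 2, data_range = 2), 1)
  expect_error(ssim(a, a[1:10, 1:10]), "identical dimensions")
})

test_that("SSIM agrees with the frozen cross-implementation reference", {
  # reference value computed with scikit-image structural_similarity
  # (gaussian_weights, sigma = 1.5, use_sample_covariance = FALSE,
  # data_range = joint min-max) on this exact seeded pair
  set.seed(7)
  a <- matrix(runif(64 * 64), 64, 64)
  b <- a + 0.1 * matrix(rnorm(64 * 64), 64, 64)
  expect_equal(ssim(a, b), 0.9433820733, tolerance = 1e-6)
})

test_that("masked SSIM averages over the valid interior only", {
  set.seed(8)
  a <- matrix(runif(40 * 40, 1, 2), 40, 40)
  mask <- matrix(TRUE, 40, 40); mask[1:10, ] <- FALSE
  expect_equal(ssim(a, a, mask = mask), 1, tolerance = 1e-9)
  m1 <- lifetime_map(a, mask, matrix(100, 40, 40))
  b <- a; b[40, 40] <- 2.5
  m2 <- lifetime_map(b, mask, matrix(100, 40, 40))
  v <- ssim(m1, m2)
  expect_true(v < 1 && v > 0.9)
})
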