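test_that("amplitude-weighted lifetime follows the closed form", {
  expect_equal(amplitude_weighted_lifetime(decay_model(1, 4)), 4)
  expect_equal(amplitude_weighted_lifetime(decay_model(c(0.5, 0.5), c(1, 3))), 2)
  expect_equal(amplitude_weighted_lifetime(decay_model(c(0.2, 0.8), c(3, 0.5))), 1)
  expect_error(decay_model(c(0.3, 0.3), c(1, 2)), "sum to 1")
  expect_error(decay_model(c(0.5, 0.5), c(1, -2)), "positive")
})

test_that("SNR/count mapping matches Poisson shot-noise statistics", {
  expect_equal(snr_db_from_counts(100), 20)
  expect_equal(snr_db_from_counts(10000), 40)
  expect_equal(snr_db_from_counts(1), 0)
  expect_equal(counts_from_snr_db(20), 100L)
  expect_equal(counts_from_snr_db(40), 10000L)
  expect_equal(counts_from_snr_db(30), 1000L)
  expect_error(snr_db_from_counts(0), ">= 1")
  # round trip across the full benchmark count range
  y <- 100:10000
  expect_equal(counts_from_snr_db(snr_db_from_counts(y)), y)
})

test_that("delta-IRF clean curves are exactly geometric (log-linear)", {
  ax <- time_axis()
  cl <- synthesize_clean(decay_model(1, 1), irf_spec(0, t0 = 0), ax)
  expect_equal(cl[-1] / cl[-ax$n_bins], rep(exp(-ax$bin_width), ax$n_bins - 1),
               tolerance = 1e-12)
  # log-linearity: slope -1/tau, essentially perfect fit
  tt <- axis_times(ax)
  fit <- lm(log(cl) ~ tt)
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 1e-9)
  expect_gt(suppressWarnings(summary(fit))$r.squared, 1 - 1e-12)
})

test_that("Gaussian-IRF clean curves match the analytic convolution", {
  ax <- time_axis()
  irf <- irf_spec(167)
  t0 <- 0.1 * ax$window
  cases <- list(list(a = 1, t = 2),
                list(a = c(0.3, 0.7), t = c(0.6, 3.2)),
                list(a = c(0.5, 0.5), t = c(1, 3)))
  for (cs in cases) {
    mine <- synthesize_clean(decay_model(cs$a, cs$t), irf, ax)
    oracle <- emg_clean_oracle(cs$a, cs$t, ax, 167, t0)
    expect_lt(max(abs(mine - oracle)) / max(oracle), 1e-3)
  }
})

test_that("clean-curve mass approximates amplitude times window mass", {
  ax <- time_axis()
  m <- decay_model(c(0.5, 0.5), c(1, 3), amplitude = 2)
  cl <- synthesize_clean(m, irf_spec(167), ax)
  mass <- 2 * (0.5 * 1 * (1 - exp(-ax$window / 1)) +
                 0.5 * 3 * (1 - exp(-ax$window / 3)))
  # the IRF delays the decay by ~1 ns, so a small tail fraction leaves the window
  expect_equal(sum(cl), mass, tolerance = 0.03)
})

test_that("convolution is linear in the decay components", {
  ax <- time_axis()
  irf <- irf_spec(167)
  mix <- synthesize_clean(decay_model(c(0.5, 0.5), c(1, 3)), irf, ax)
  c1 <- synthesize_clean(decay_model(1, 1), irf, ax)
  c3 <- synthesize_clean(decay_model(1, 3), irf, ax)
  expect_lt(max(abs(mix - 0.5 * c1 - 0.5 * c3)) / max(mix), 1e-10)
})

test_that("IRF validation and warnings fire", {
  ax <- time_axis(32L, 0.039)
  expect_warning(synthesize_clean(decay_model(1, 1), irf_spec(5000, t0 = 0.5), ax),
                 "FWHM exceeds")
  expect_error(irf_t0(irf_spec(167, t0 = 99), ax), "outside the time window")
  expect_error(time_axis(1L), ">= 2")
})

test_that("Poisson sampling conserves the photon budget and is seedable", {
  ax <- time_axis()
  clean <- synthesize_clean(decay_model(1, 1), irf_spec(167), ax)
  h1 <- sample_histogram(clean, 10000, ax, seed = 5)
  h2 <- sample_histogram(clean, 10000, ax, seed = 5)
  expect_identical(h1$counts, h2$counts)
  expect_lt(abs(h1$total_counts - 10000), 3 * sqrt(10000))
  # Monte-Carlo Poisson property: per-bin variance tracks per-bin mean
  set.seed(42)
  bin <- which.max(clean)
  reps <- replicate(3000, sample_histogram(clean, 2000, ax)$counts[bin])
  expect_equal(var(reps), mean(reps), tolerance = 0.1)
  expect_error(sample_histogram(numeric(ax$n_bins), 100, ax), "zero")
})

test_that("generated datasets respect the declared study conditions", {
  ds <- tiny_dataset(n = 400L, seed = 21L)
  expect_equal(nrow(ds$histograms), 400L)
  expect_true(all(ds$labels >= 0.1 & ds$labels <= 5))
  expect_true(all(ds$histograms >= 0))
  mono <- ds$params$n_components == 1L
  expect_true(all(ds$params$tau1[!mono] >= 0.1 & ds$params$tau1[!mono] <= 1))
  expect_true(all(ds$params$tau2[!mono] >= 1 & ds$params$tau2[!mono] <= 5))
  expect_true(all(ds$params$fwhm_ps >= 20))
  expect_true(all(ds$params$target_counts >= 100 &
                    ds$params$target_counts <= 10000))
})

test_that("identical dataset specs give bitwise-identical datasets", {
  d1 <- tiny_dataset(n = 50L, seed = 33L)
  d2 <- tiny_dataset(n = 50L, seed = 33L)
  expect_identical(d1$histograms, d2$histograms)
  expect_identical(d1$labels, d2$labels)
  d3 <- tiny_dataset(n = 50L, seed = 34L)
  expect_false(identical(d1$histograms, d3$histograms))
})

test_that("label distribution matches the analytic mixture of the draws", {
  ds <- generate_dataset(dataset_spec(4000, seed = 77,
                                      axis = time_axis(64L, 0.156)))
  # independent Monte-Carlo reference for tau_A = alpha tau1 + (1-alpha) tau2
  set.seed(1234)
  n <- 4e4
  mono <- runif(n) < 0.5
  ref <- ifelse(mono, runif(n, 0.1, 5), {
    a <- runif(n)
    a * runif(n, 0.1, 1) + (1 - a) * runif(n, 1, 5)
  })
  ks <- suppressWarnings(ks.test(ds$labels, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("dataset CSV serialization round-trips", {
  ds <- tiny_dataset(n = 20L, seed = 3L)
  prefix <- file.path(withr::local_tempdir(), "ds")
  write_dataset(ds, prefix)
  back <- read_dataset(prefix)
  expect_identical(back$histograms, ds$histograms)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$axis$bin_width, ds$axis$bin_width)
  expect_error(read_dataset(file.path(tempdir(), "nope")), "missing dataset")
})
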