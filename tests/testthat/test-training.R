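test_that("peak normalization is exact, idempotent, and scale-free", {
  expect_equal(normalize_histogram(c(0, 5, 10, 2)), c(0, 0.5, 1, 0.2))
  x <- c(3, 9, 1)
  expect_equal(normalize_histogram(normalize_histogram(x)),
               normalize_histogram(x))
  expect_equal(normalize_histogram(7 * x), normalize_histogram(x))
  expect_error(normalize_histogram(c(0, 0)), "all-zero")
})

test_that("MSE loss matches hand arithmetic and is permutation-invariant", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(1, 2), c(2, 2)), 0.5)
  p <- runif(10); l <- runif(10)
  o <- sample(10)
  expect_equal(mse_loss(p, l), mse_loss(p[o], l[o]))
  expect_error(mse_loss(1:3, 1:2), "equal length")
})

test_that("training memorizes a degenerate dataset", {
  ax <- time_axis(64L, 0.156)
  clean <- synthesize_clean(decay_model(1, 2), irf_spec(167), ax)
  h <- sample_histogram(clean, 3000, ax, seed = 1)
  ds <- list(histograms = matrix(rep(h$counts, each = 120), 120),
             labels = rep(2, 120))
  cfg <- train_config(learning_rate = 3e-3, batch_size = 30L,
                      max_epochs = 60L, seed = 5)
  fit <- train_mixer(ds, cfg)
  expect_lt(fit$best_val_mse, 1e-3)
  expect_lt(fit$best_val_mse, fit$history$val_mse[1] / 100)
})

test_that("training is reproducible for a fixed seed", {
  ds <- tiny_dataset(n = 120L, seed = 9L)
  cfg <- train_config(batch_size = 40L, max_epochs = 3L, seed = 17)
  f1 <- train_mixer(ds, cfg)
  f2 <- train_mixer(ds, cfg)
  expect_identical(f1$history, f2$history)
  x <- normalize_histogram(ds$histograms[1, ])
  expect_identical(mixer_forward(f1$network, x), mixer_forward(f2$network, x))
})

test_that("early stopping and best-weight contracts hold", {
  ds <- tiny_dataset(n = 150L, seed = 13L)
  cfg <- train_config(learning_rate = 2e-3, batch_size = 50L,
                      early_stop_patience = 3L, max_epochs = 60L, seed = 23)
  fit <- train_mixer(ds, cfg)
  n_epochs <- nrow(fit$history)
  expect_lte(n_epochs - fit$best_epoch, 3L)
  expect_equal(fit$best_val_mse, min(fit$history$val_mse))
  # the returned network really is the best-validation-epoch snapshot
  xn <- ds$histograms / apply(ds$histograms, 1, max)
  preds <- mixer_forward(fit$network, xn[fit$val_idx, ])
  expect_equal(mse_loss(preds, ds$labels[fit$val_idx]), fit$best_val_mse,
               tolerance = 1e-10)
})

test_that("degenerate training inputs are rejected", {
  ds <- tiny_dataset(n = 30L, seed = 2L)
  expect_error(train_mixer(ds, train_config(batch_size = 200L, seed = 1)),
               "smaller than one batch")
  expect_error(train_config(val_fraction = 1.2), "val_fraction")
  expect_error(train_config(learning_rate = -1), "positive")
})
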