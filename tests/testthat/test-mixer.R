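test_that("patchify pads and reshapes reversibly", {
  p <- patchify(numeric(256), 10)
  expect_equal(dim(p), c(26L, 10L))
  x <- runif(256)
  p <- patchify(x, 10)
  expect_equal(sum(p[26, 7:10] != 0), 0)  # 4-bin tail padding is zero
  expect_equal(as.numeric(t(p))[1:256], x)  # concatenation recovers input
  p2 <- patchify(runif(250), 10)
  expect_equal(dim(p2), c(25L, 10L))
  expect_error(patchify(x, 0), "positive")
})

test_that("network parameter count matches the layer-by-layer closed form", {
  cfg <- mixer_config()
  net <- mixer_network(cfg, input_length = 256L)
  n_p <- 26L; C <- 16L
  expected <- (10 * C + C) +                                   # embedding
    (2 * C + (n_p * 16 + 16) + (16 * n_p + n_p) +              # ln1 + token MLP
       2 * C + (C * 16 + 16) + (16 * C + C)) +                 # ln2 + channel MLP
    (n_p * C * 64 + 64) + (64 * 32 + 32) + (32 * 1 + 1)        # regression head
  expect_equal(count_parameters(net), expected)
  expect_identical(count_parameters(net), 30459L)
  wide <- mixer_network(mixer_config(channel_dim = 32L), input_length = 256L)
  expect_gt(count_parameters(wide), count_parameters(net))
  expect_error(mixer_config(head_widths = integer(0)), "at least one")
})

test_that("forward pass is deterministic and shape-correct at inference", {
  net <- mixer_network(tiny_config(), input_length = 23L, seed = 4)
  x <- matrix(runif(6 * 23), 6, 23)
  y1 <- mixer_forward(net, x)
  y2 <- mixer_forward(net, x)
  expect_length(y1, 6L)
  expect_identical(y1, y2)
  # identical rows give identical outputs regardless of batch position
  xx <- rbind(x[1, ], x, x[1, ])
  yy <- mixer_forward(net, xx)
  expect_equal(yy[1], yy[length(yy)])
  expect_equal(yy[1], y1[1])
  expect_error(mixer_forward(net, matrix(0, 2, 10)), "does not match")
})

test_that("zeroed mixer output layers reduce each block to the identity", {
  cfg <- tiny_config()
  net <- mixer_network(cfg, input_length = 20L, seed = 8)
  net$params$block1$tok2$W[] <- 0
  net$params$block1$tok2$b[] <- 0
  net$params$block1$ch2$W[] <- 0
  net$params$block1$ch2$b[] <- 0
  x <- matrix(runif(3 * 20), 3, 20)
  fm <- asNamespace("flimmixer")
  cache <- fm$mixer_fwd(net, x, cache = TRUE)
  # embeddings computed directly from patches must survive the block unchanged
  E0 <- cache$blocks[[1]]$E
  n_p <- net$n_patches; C <- cfg$channel_dim
  E_after <- matrix(aperm(array(t(cache$Fm), c(n_p, C, nrow(x))), c(1, 3, 2)),
                    nrow = n_p * nrow(x))
  expect_lt(max(abs(E_after - E0)), 1e-6)
})

test_that("analytic gradients agree with finite differences", {
  fm <- asNamespace("flimmixer")
  set.seed(1)
  net <- mixer_network(tiny_config(), input_length = 23L, seed = 2)
  x <- matrix(runif(3 * 23), 3, 23)
  y <- c(1, 2, 3)
  cache <- fm$mixer_fwd(net, x, cache = TRUE)
  grad <- fm$mixer_bwd(net, cache, 2 * (cache$y - y) / 3)
  gflat <- fm$flatten_params(grad)
  pflat <- fm$flatten_params(net$params)
  eps <- 1e-6
  loss_at <- function(flat) {
    n2 <- net
    n2$params <- fm$assign_flat(net$params, flat)
    mean((fm$mixer_fwd(n2, x) - y)^2)
  }
  for (k in names(pflat)) {
    idx <- sample(length(pflat[[k]]), min(2L, length(pflat[[k]])))
    for (i in idx) {
      p2 <- pflat; p2[[k]][i] <- p2[[k]][i] + eps
      up <- loss_at(p2)
      p2[[k]][i] <- p2[[k]][i] - 2 * eps
      dn <- loss_at(p2)
      num <- (up - dn) / (2 * eps)
      expect_equal(gflat[[k]][i], num, tolerance = 1e-4)
      # every parameter receives a finite gradient (no dead layers at init)
      expect_true(all(is.finite(gflat[[k]])))
    }
  }
})

test_that("compiled and reference implementations agree to machine precision", {
  fm <- asNamespace("flimmixer")
  set.seed(10)
  net <- mixer_network(input_length = 256L, seed = 9)
  x <- matrix(runif(20 * 256), 20, 256)
  y <- runif(20, 0.1, 5)
  expect_equal(mixer_forward(net, x, engine = "cpp"),
               mixer_forward(net, x, engine = "r"), tolerance = 1e-12)
  xp <- cbind(x, matrix(0, 20, net$padded_length - 256L))
  # inference mode on both paths so no dropout masks are drawn
  cache <- fm$mixer_fwd(net, x, training = FALSE, cache = TRUE)
  gr <- fm$flatten_params(fm$mixer_bwd(net, cache, 2 * (cache$y - y) / 20))
  st <- fm$.mixer_step_cpp(net$params, xp, y, 10L, net$n_patches, 16L, 1L, 0)
  gc <- fm$flatten_params(st$grads)
  for (k in names(gr))
    expect_lt(max(abs(gr[[k]] - as.numeric(gc[[k]]))), 1e-10)
})

test_that("checkpoints round-trip the network exactly", {
  net <- mixer_network(tiny_config(), input_length = 23L, seed = 12)
  path <- file.path(withr::local_tempdir(), "model.json")
  save_checkpoint(net, path, meta = list(note = "fixture"))
  back <- load_checkpoint(path)
  x <- matrix(runif(4 * 23), 4, 23)
  expect_equal(mixer_forward(back, x), mixer_forward(net, x), tolerance = 1e-12)
  expect_identical(back$input_length, net$input_length)
  expect_error(suppressWarnings(load_checkpoint(tempfile())),
               "cannot open|No such|not a flimmixer")
})
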