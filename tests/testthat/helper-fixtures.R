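# Shared fixtures and independent oracles for the test suite.

# Closed-form convolution of a Gaussian IRF with a multiexponential decay
# (exponentially modified Gaussian), integrated per bin by a fine midpoint
# rule. Independent of the package's discrete-convolution path.
emg_clean_oracle <- function(alpha, tau, axis, fwhm_ps, t0, amplitude = 1,
                             sub = 100L) {
  sigma <- fwhm_ps / 1000 / (2 * sqrt(2 * log(2)))
  dt <- axis$bin_width / sub
  tt <- (seq_len(axis$n_bins * sub) - 0.5) * dt
  y <- 0
  for (k in seq_along(tau)) {
    u <- tt - t0
    y <- y + alpha[k] * 0.5 *
      exp(sigma^2 / (2 * tau[k]^2) - u / tau[k]) *
      pracma::erfc((sigma^2 / tau[k] - u) / (sigma * sqrt(2)))
  }
  amplitude * colSums(matrix(y, nrow = sub)) * dt
}

# A small network configuration for fast structural tests.
tiny_config <- function(dropout = 0) {
  mixer_config(patch_size = 5L, channel_dim = 4L, token_hidden = 3L,
               channel_hidden = 3L, dropout_rate = dropout,
               head_widths = c(6L, 4L))
}

# A quick noiseless histogram from the simulator at a large photon budget.
noiseless_histogram <- function(model, irf = irf_spec(167),
                                axis = time_axis(), counts = 1e6) {
  clean <- synthesize_clean(model, irf, axis)
  decay_histogram(round(clean * (counts / sum(clean))), axis)
}

# Small deterministic training set: mono decays on a short axis.
tiny_dataset <- function(n = 300L, seed = 11L, axis = time_axis(64L, 0.156)) {
  generate_dataset(dataset_spec(n, seed = seed, axis = axis))
}
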