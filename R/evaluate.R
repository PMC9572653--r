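#' Relative bias of a set of estimates
#'
#' `|mean(estimates) - truth| / truth`: the bias of the mean estimator for
#' a benchmark cell, as a unitless fraction.
#'
#' @param estimates Non-empty numeric vector of lifetime estimates (ns).
#' @param truth True lifetime (> 0, ns).
#' @return Unitless relative bias (>= 0).
#' @export
relative_bias <- function(estimates, truth) {
  if (length(estimates) < 1L || any(!is.finite(estimates)))
    stop("`estimates` must be non-empty and finite")
  if (length(truth) != 1L || !is.finite(truth) || truth <= 0)
    stop("`truth` must be a single positive number")
  abs(mean(estimates) - truth) / truth
}

#' Standard deviation around the truth
#'
#' `sqrt(sum((estimates - truth)^2) / (n - 1))`: the spread of the
#' estimates measured around the true value (an RMSE-like quantity with an
#' n-1 denominator), not around their own mean, so it absorbs bias as well
#' as variance.
#'
#' @inheritParams relative_bias
#' @return Spread in ns (>= 0).
#' @export
std_around_truth <- function(estimates, truth) {
  n <- length(estimates)
  if (n < 2L || any(!is.finite(estimates)))
    stop("`estimates` must contain at least two finite values")
  if (length(truth) != 1L || !is.finite(truth))
    stop("`truth` must be a single number")
  sqrt(sum((estimates - truth)^2) / (n - 1))
}

# Run one estimation method over a set of simulated histograms.
# `hists` is a list of flim_decay_histogram; `irfs` a list of flim_irf.
estimate_with <- function(method, network, hists, irfs, n_components = 1L) {
  if (method == "mixer") {
    if (is.null(network)) stop("a trained `network` is required for method 'mixer'")
    counts <- do.call(rbind, lapply(hists, `[[`, "counts"))
    return(predict_lifetime(network, counts))
  }
  vapply(seq_along(hists), function(i) {
    h <- hists[[i]]; ir <- irfs[[i]]
    switch(method,
      nlsm = fit_nlsm(h, ir, n_components)$tau_a,
      vpm  = fit_vpm(h, ir, n_components)$tau_a,
      cmm  = fit_cmm(h, irf_t0(ir, h$axis)),
      stop("unknown method: ", method))
  }, numeric(1))
}

# Draw per-replicate IRFs from the training FWHM distribution.
draw_irfs <- function(n, fwhm_mean = 167, fwhm_sd = 60, fwhm_floor = 20) {
  fw <- pmax(fwhm_floor, stats::rnorm(n, fwhm_mean, fwhm_sd))
  lapply(fw, irf_spec)
}

#' Monoexponential benchmark sweep
#'
#' For each true lifetime and SNR bin, simulates `n_replicates` histograms
#' (photon budget drawn uniformly in dB within the bin, IRF FWHM drawn from
#' the training distribution), runs every requested method, and tabulates
#' the mean estimate, relative bias, and standard deviation around truth.
#'
#' @param methods Character vector from `c("mixer", "nlsm", "vpm", "cmm")`.
#' @param lifetimes True lifetimes in ns.
#' @param snr_bins List of `c(low, high)` SNR intervals in dB.
#' @param n_replicates Histograms per (lifetime, bin) cell.
#' @param network Trained [mixer_network()] (required when "mixer" is
#'   among `methods`).
#' @param axis A `flim_time_axis`.
#' @param seed RNG seed; results are deterministic given (seed, network).
#' @return A data frame of class `flim_metric_table` with one row per
#'   (method, lifetime, bin): `method`, `tau_true`, `snr_lo`, `snr_hi`,
#'   `mean_estimate`, `bias`, `std`, `n`.
#' @export
run_mono_benchmark <- function(methods, lifetimes = c(1, 4),
                               snr_bins = list(c(20, 32), c(32, 38), c(38, 40)),
                               n_replicates = 500L, network = NULL,
                               axis = time_axis(), seed = 1L) {
  if ("mixer" %in% methods && is.null(network))
    stop("method 'mixer' needs a trained `network`")
  if (n_replicates < 2L) stop("`n_replicates` must be >= 2")
  with_local_seed(seed, {
    rows <- list()
    for (tau in lifetimes) {
      model <- decay_model(1, tau)
      for (bin in snr_bins) {
        snr <- stats::runif(n_replicates, bin[1], bin[2])
        counts <- counts_from_snr_db(snr)
        irfs <- draw_irfs(n_replicates)
        hists <- lapply(seq_len(n_replicates), function(i) {
          clean <- synthesize_clean(model, irfs[[i]], axis)
          lam <- clean * (counts[i] / sum(clean))
          decay_histogram(stats::rpois(axis$n_bins, lam), axis)
        })
        for (m in methods) {
          est <- estimate_with(m, network, hists, irfs, n_components = 1L)
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, tau_true = tau, snr_lo = bin[1], snr_hi = bin[2],
            mean_estimate = mean(est),
            bias = relative_bias(est, tau),
            std = std_around_truth(est, tau),
            n = n_replicates)
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("flim_metric_table", class(out))
    out
  })
}

#' Biexponential benchmark sweep
#'
#' For each (alpha, SNR) cell, simulates histograms with component
#' lifetimes drawn uniformly from `tau1_range` x `tau2_range`, compares
#' each method's estimate to the per-replicate amplitude-weighted truth,
#' and tabulates the cell bias `|mean(est - truth)| / mean(truth)`, the
#' mean absolute relative error, and the spread of `est - truth`.
#'
#' @param methods Character vector from `c("mixer", "nlsm", "vpm", "cmm")`.
#' @param alpha_values Fractions of the short-lifetime component.
#' @param snr_points_db SNR test points in dB (exact photon budgets).
#' @param n_per_cell Histograms per (alpha, SNR) cell.
#' @param tau1_range,tau2_range Uniform component-lifetime ranges (ns).
#' @param network Trained mixer (required for method "mixer").
#' @param axis A `flim_time_axis`.
#' @param seed RNG seed.
#' @return A data frame of class `flim_metric_table`, one row per (method,
#'   alpha, snr): `mean_truth`, `mean_estimate`, `bias`,
#'   `mean_abs_rel_error`, `std`, `n`.
#' @export
run_bi_benchmark <- function(methods, alpha_values = c(0.2, 0.5, 0.8),
                             snr_points_db = c(26, 34, 38),
                             n_per_cell = 300L,
                             tau1_range = c(0.5, 1.5),
                             tau2_range = c(2.5, 3.5),
                             network = NULL, axis = time_axis(), seed = 1L) {
  if ("mixer" %in% methods && is.null(network))
    stop("method 'mixer' needs a trained `network`")
  if (n_per_cell < 2L) stop("`n_per_cell` must be >= 2")
  with_local_seed(seed, {
    rows <- list()
    for (alpha in alpha_values) {
      for (snr in snr_points_db) {
        counts <- counts_from_snr_db(snr)
        tau1 <- stats::runif(n_per_cell, tau1_range[1], tau1_range[2])
        tau2 <- stats::runif(n_per_cell, tau2_range[1], tau2_range[2])
        truth <- alpha * tau1 + (1 - alpha) * tau2
        irfs <- draw_irfs(n_per_cell)
        hists <- lapply(seq_len(n_per_cell), function(i) {
          model <- if (alpha >= 1) decay_model(1, tau1[i]) else
            decay_model(c(alpha, 1 - alpha), c(tau1[i], tau2[i]))
          clean <- synthesize_clean(model, irfs[[i]], axis)
          lam <- clean * (counts / sum(clean))
          decay_histogram(stats::rpois(axis$n_bins, lam), axis)
        })
        for (m in methods) {
          est <- estimate_with(m, network, hists, irfs, n_components = 2L)
          err <- est - truth
          rows[[length(rows) + 1L]] <- data.frame(
            method = m, alpha = alpha, snr_db = snr,
            mean_truth = mean(truth), mean_estimate = mean(est),
            bias = abs(mean(err)) / mean(truth),
            mean_abs_rel_error = mean(abs(err) / truth),
            std = stats::sd(err), n = n_per_cell)
        }
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("flim_metric_table", class(out))
    out
  })
}

#' Pooled relative bias from a biexponential metric table
#'
#' Pools the per-cell signed errors of one method across SNR points for a
#' given alpha: `|sum n*(mean_est - mean_truth)| / sum n*mean_truth`.
#'
#' @param table A metric table from [run_bi_benchmark()].
#' @param method Method name to pool.
#' @param alpha Alpha value to pool.
#' @return Unitless pooled relative bias.
#' @export
pooled_bi_bias <- function(table, method, alpha) {
  rows <- table[table$method == method & table$alpha == alpha, ]
  if (nrow(rows) < 1L) stop("no matching rows in `table`")
  abs(sum(rows$n * (rows$mean_estimate - rows$mean_truth))) /
    sum(rows$n * rows$mean_truth)
}

# Separable Gaussian filter with symmetric ('reflect') boundary handling,
# kernel radius floor(truncate*sigma + 0.5).
gaussian_filter2d <- function(x, sigma, truncate = 3.5) {
  r <- as.integer(truncate * sigma + 0.5)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  reflect_pad <- function(v, r) c(rev(v[seq_len(r)]), v,
                                  rev(v[length(v) - seq_len(r) + 1L]))
  filt1 <- function(v) {
    vp <- reflect_pad(v, r)
    stats::convolve(vp, k, type = "filter")
  }
  x <- apply(x, 2L, filt1)
  t(apply(x, 1L, filt1))
}

#' Structural similarity index of two lifetime maps
#'
#' Mean SSIM with Gaussian windowing (sigma 1.5, 11 x 11 support) and the
#' standard stabilization constants (K1 = 0.01, K2 = 0.03). Unless given,
#' the data range is the joint min-max of the two maps. With a validity
#' mask, masked pixels are filled with the mean of each map's valid pixels
#' before windowing (limiting edge artifacts) and the SSIM map is averaged
#' over the valid interior only.
#'
#' @param a,b Equal-sized numeric matrices (or `flim_lifetime_map` objects,
#'   whose masks are intersected).
#' @param mask Optional logical matrix of valid pixels.
#' @param data_range Dynamic range used in the stabilization constants.
#' @return Mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, mask = NULL, data_range = NULL) {
  if (inherits(a, "flim_lifetime_map") || inherits(b, "flim_lifetime_map")) {
    stopifnot(inherits(a, "flim_lifetime_map"),
              inherits(b, "flim_lifetime_map"))
    m <- a$mask & b$mask
    if (is.null(mask)) mask <- m else mask <- mask & m
    a <- a$tau_a; b <- b$tau_a
  }
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("`a` and `b` must be matrices of identical dimensions")
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(a))) stop("`mask` must match the map dimensions")
    if (!any(mask)) stop("mask excludes every pixel")
    a[!mask] <- mean(a[mask]); b[!mask] <- mean(b[mask])
  }
  if (is.null(data_range)) {
    data_range <- max(a, b) - min(a, b)
    if (data_range <= 0) data_range <- 1
  }
  sigma <- 1.5; truncate <- 3.5
  r <- as.integer(truncate * sigma + 0.5)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  ux <- gaussian_filter2d(a, sigma, truncate)
  uy <- gaussian_filter2d(b, sigma, truncate)
  uxx <- gaussian_filter2d(a * a, sigma, truncate)
  uyy <- gaussian_filter2d(b * b, sigma, truncate)
  uxy <- gaussian_filter2d(a * b, sigma, truncate)
  vx <- uxx - ux * ux
  vy <- uyy - uy * uy
  vxy <- uxy - ux * uy
  S <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux * ux + uy * uy + c1) * (vx + vy + c2))
  keep_i <- (r + 1L):(nrow(S) - r)
  keep_j <- (r + 1L):(ncol(S) - r)
  if (length(keep_i) < 1L || length(keep_j) < 1L)
    stop("maps are too small for the SSIM window")
  S <- S[keep_i, keep_j, drop = FALSE]
  if (!is.null(mask)) {
    m <- mask[keep_i, keep_j, drop = FALSE]
    if (!any(m)) stop("mask excludes the whole SSIM interior")
    mean(S[m])
  } else {
    mean(S)
  }
}
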