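#' TCSPC time axis
#'
#' A uniform time axis for TCSPC decay histograms. The default matches a
#' typical Becker & Hickl acquisition: 256 bins of 0.039 ns (a 9.984 ns
#' window at an 80 MHz excitation rate).
#'
#' @param n_bins Number of time bins (integer, >= 2).
#' @param bin_width Bin duration in nanoseconds (> 0).
#' @return An object of class `flim_time_axis` with fields `n_bins`,
#'   `bin_width`, and the derived `window` (= `n_bins * bin_width`, ns).
#' @export
#' @examples
#' ax <- time_axis()
#' ax$window
time_axis <- function(n_bins = 256L, bin_width = 0.039) {
  n_bins <- as.integer(n_bins)
  if (length(n_bins) != 1L || is.na(n_bins) || n_bins < 2L)
    stop("`n_bins` must be a single integer >= 2")
  if (length(bin_width) != 1L || !is.finite(bin_width) || bin_width <= 0)
    stop("`bin_width` must be a single positive number (ns)")
  structure(
    list(n_bins = n_bins, bin_width = bin_width, window = n_bins * bin_width),
    class = "flim_time_axis"
  )
}

#' Bin-center times of an axis
#'
#' @param axis A `flim_time_axis`.
#' @return Numeric vector of bin-center times in ns.
#' @export
axis_times <- function(axis) {
  stopifnot(inherits(axis, "flim_time_axis"))
  (seq_len(axis$n_bins) - 0.5) * axis$bin_width
}

#' Gaussian instrument response function specification
#'
#' The instrument response function (IRF) is modelled as a Gaussian pulse.
#' `fwhm = 0` denotes an ideal delta IRF (useful for closed-form checks).
#'
#' @param fwhm Full width at half maximum in picoseconds (>= 0; 0 = delta).
#' @param t0 Peak position on the time axis in nanoseconds. `NA` (default)
#'   places the peak 10% into the acquisition window, so the full rising
#'   edge of the decay is captured.
#' @return An object of class `flim_irf`.
#' @export
irf_spec <- function(fwhm = 167, t0 = NA_real_) {
  if (length(fwhm) != 1L || !is.finite(fwhm) || fwhm < 0)
    stop("`fwhm` must be a single non-negative number (ps)")
  if (length(t0) != 1L || (!is.na(t0) && !is.finite(t0)))
    stop("`t0` must be a single number (ns) or NA")
  structure(list(fwhm = fwhm, t0 = t0), class = "flim_irf")
}

# Resolve the IRF peak position against an axis (default: 10% into window).
irf_t0 <- function(irf, axis) {
  t0 <- if (is.na(irf$t0)) 0.1 * axis$window else irf$t0
  if (t0 < 0 || t0 > axis$window)
    stop(sprintf("IRF peak t0 = %g ns lies outside the time window [0, %g] ns",
                 t0, axis$window))
  t0
}

#' Multiexponential decay model
#'
#' Ground-truth parameters of a decay y(t) = A * sum_i alpha_i exp(-t/tau_i),
#' with the fractions constrained to sum to one.
#'
#' @param alpha Numeric vector of component fractions in `[0, 1]`, summing
#'   to 1 (within 1e-12).
#' @param tau Numeric vector of component lifetimes in ns (> 0), same
#'   length as `alpha`.
#' @param amplitude Overall decay amplitude A (> 0). The photon budget of a
#'   simulated histogram is set separately, so `amplitude` is provenance
#'   only; it scales the clean curve but not sampled counts.
#' @return An object of class `flim_decay_model`.
#' @export
#' @examples
#' decay_model(c(0.2, 0.8), c(3, 0.5))
decay_model <- function(alpha, tau, amplitude = 1) {
  if (length(alpha) != length(tau) || length(alpha) < 1L)
    stop("`alpha` and `tau` must be non-empty vectors of equal length")
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("all fractions `alpha` must lie in [0, 1]")
  if (abs(sum(alpha) - 1) > 1e-12)
    stop(sprintf("component fractions must sum to 1 (got %.15g)", sum(alpha)))
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all lifetimes `tau` must be positive (ns)")
  if (length(amplitude) != 1L || !is.finite(amplitude) || amplitude <= 0)
    stop("`amplitude` must be a single positive number")
  structure(list(alpha = as.numeric(alpha), tau = as.numeric(tau),
                 amplitude = amplitude),
            class = "flim_decay_model")
}

#' Amplitude-weighted average lifetime
#'
#' The fraction-weighted mean lifetime tau_A = sum_i alpha_i tau_i. This is
#' the quantity the mixer network regresses and the label used throughout
#' the benchmarks; it is distinct from the intensity-weighted average that
#' the center-of-mass method reports.
#'
#' @param model A `flim_decay_model`.
#' @return Lifetime in ns.
#' @export
#' @examples
#' amplitude_weighted_lifetime(decay_model(c(0.5, 0.5), c(1, 3)))  # 2 ns
amplitude_weighted_lifetime <- function(model) {
  stopifnot(inherits(model, "flim_decay_model"))
  sum(model$alpha * model$tau)
}

#' Photon-count SNR in decibels
#'
#' For Poisson photon statistics the signal-to-noise ratio is sqrt(Y) for a
#' total of Y detected photons, giving SNR(dB) = 20 log10(sqrt(Y)) =
#' 10 log10(Y). Under this convention 100 photons correspond to 20 dB and
#' 10,000 photons to 40 dB.
#'
#' @param total_counts Total photon count(s), >= 1.
#' @return SNR in dB (vectorized).
#' @export
snr_db_from_counts <- function(total_counts) {
  if (length(total_counts) < 1L || any(!is.finite(total_counts)) ||
      any(total_counts < 1))
    stop("`total_counts` must be >= 1")
  10 * log10(total_counts)
}

#' Photon count for a target SNR
#'
#' Inverse of [snr_db_from_counts()]: the (rounded) total photon count whose
#' shot-noise SNR equals `snr` dB.
#'
#' @param snr SNR in dB (vectorized).
#' @return Integer photon counts.
#' @export
counts_from_snr_db <- function(snr) {
  if (length(snr) < 1L || any(!is.finite(snr)))
    stop("`snr` must be finite")
  as.integer(round(10^(snr / 10)))
}

# Linear (acyclic) convolution via FFT; returns the first length(x) samples,
# i.e. the causal part on the grid of x.
conv_causal <- function(x, k) {
  n <- length(x) + length(k) - 1L
  m <- stats::nextn(n, 2)
  xf <- stats::fft(c(x, numeric(m - length(x))))
  kf <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(xf * kf, inverse = TRUE))[seq_along(x)] / m
}

# Discretized Gaussian IRF kernel, unit sum. Sampled at offsets (i-1)*dt so
# that convolving with a decay sampled at bin centers stays center-aligned
# (no half-sample shift). fwhm = 0 yields a discrete delta nearest t0.
irf_kernel <- function(irf, axis, t_os, dt) {
  t_os <- t_os - dt / 2
  t0 <- irf_t0(irf, axis)
  if (irf$fwhm <= 0) {
    k <- numeric(length(t_os))
    k[which.min(abs(t_os - t0))] <- 1
    return(k)
  }
  fwhm_ns <- irf$fwhm / 1000
  if (fwhm_ns > axis$window)
    warning("IRF FWHM exceeds the acquisition window; the convolved decay is severely smeared")
  sigma <- fwhm_ns / (2 * sqrt(2 * log(2)))
  k <- exp(-0.5 * ((t_os - t0) / sigma)^2)
  k / sum(k)
}

#' Noise-free convolved decay curve
#'
#' Expected (clean) counts per bin for a multiexponential decay convolved
#' with a Gaussian IRF: IRF(t) * A sum_i alpha_i exp(-t/tau_i), evaluated by
#' linear discrete convolution at `oversample`x temporal oversampling and
#' re-binned to the axis. Values are midpoint-quadrature integrals per bin,
#' so the curve sums approximately to `amplitude` times the decay mass
#' inside the window.
#'
#' @param model A `flim_decay_model`.
#' @param irf A `flim_irf` (use `fwhm = 0` for an ideal delta IRF).
#' @param axis A `flim_time_axis`.
#' @param oversample Temporal oversampling factor controlling discretization
#'   error of the continuous convolution (default 4).
#' @return Numeric vector of `axis$n_bins` non-negative expected counts.
#' @export
synthesize_clean <- function(model, irf, axis, oversample = 4L) {
  stopifnot(inherits(model, "flim_decay_model"), inherits(irf, "flim_irf"),
            inherits(axis, "flim_time_axis"))
  oversample <- as.integer(oversample)
  if (is.na(oversample) || oversample < 1L)
    stop("`oversample` must be a positive integer")
  n_os <- axis$n_bins * oversample
  dt <- axis$bin_width / oversample
  t_os <- (seq_len(n_os) - 0.5) * dt
  decay <- model$amplitude *
    drop(exp(-outer(t_os, 1 / model$tau)) %*% model$alpha)
  k <- irf_kernel(irf, axis, t_os, dt)
  y <- if (irf$fwhm <= 0 && which.max(k) == 1L) decay else conv_causal(decay, k)
  y[y < 0] <- 0  # clip FFT round-off
  colSums(matrix(y, nrow = oversample)) * dt
}

#' TCSPC decay histogram
#'
#' @param counts Length-`axis$n_bins` vector of non-negative integer counts.
#' @param axis A `flim_time_axis`.
#' @return An object of class `flim_decay_histogram` with fields `counts`,
#'   `axis`, `total_counts`.
#' @export
decay_histogram <- function(counts, axis) {
  stopifnot(inherits(axis, "flim_time_axis"))
  if (length(counts) != axis$n_bins)
    stop("`counts` length must equal `axis$n_bins`")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9))
    stop("`counts` must be non-negative integers")
  counts <- as.integer(round(counts))
  structure(list(counts = counts, axis = axis,
                 total_counts = sum(counts)),
            class = "flim_decay_histogram")
}

#' Sample a Poisson-noise histogram from a clean curve
#'
#' Rescales the clean curve so its sum equals `target_counts` and draws an
#' independent Poisson count per bin, the dominant noise process in TCSPC.
#' The realized total fluctuates around `target_counts` with Poisson spread.
#'
#' @param clean Non-negative expected-count curve (e.g. from
#'   [synthesize_clean()]).
#' @param target_counts Expected total photon count (>= 1).
#' @param axis A `flim_time_axis` matching `clean`.
#' @param seed Optional integer; when given, the draw is made under this
#'   seed and the caller's RNG state is left untouched.
#' @return A `flim_decay_histogram`.
#' @export
sample_histogram <- function(clean, target_counts, axis, seed = NULL) {
  stopifnot(inherits(axis, "flim_time_axis"))
  if (length(clean) != axis$n_bins)
    stop("`clean` length must equal `axis$n_bins`")
  if (any(!is.finite(clean)) || any(clean < 0))
    stop("`clean` must be non-negative and finite")
  if (sum(clean) <= 0)
    stop("`clean` must not be identically zero")
  if (length(target_counts) != 1L || !is.finite(target_counts) ||
      target_counts < 1)
    stop("`target_counts` must be a single number >= 1")
  lambda <- clean * (target_counts / sum(clean))
  counts <- with_local_seed(seed, stats::rpois(length(lambda), lambda))
  decay_histogram(counts, axis)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream
# (no-op when seed is NULL).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation dataset specification
#'
#' Study conditions for training/benchmark data generation: a mixture of
#' mono- and biexponential decays with lifetimes drawn uniformly from
#' `[0.1, 5]` ns (mono) and `[0.1, 1]` x `[1, 5]` ns (bi), IRF FWHM drawn
#' from Normal(167, 60) ps truncated below, and photon budgets drawn
#' uniformly in dB over 20-40 dB (100-10,000 counts).
#'
#' @param n_signals Number of (histogram, label) pairs to generate.
#' @param seed RNG seed making the dataset fully reproducible.
#' @param mono_fraction Fraction of monoexponential signals (default 0.5).
#' @param mono_tau_range Mono lifetime range in ns.
#' @param bi_tau1_range,bi_tau2_range Biexponential component ranges in ns.
#' @param snr_range_db SNR range in dB; converted to photon counts via
#'   [counts_from_snr_db()].
#' @param irf_fwhm_mean,irf_fwhm_sd Mean/sd of the Gaussian IRF FWHM draw, ps.
#' @param irf_fwhm_floor Lower truncation of the FWHM draw, ps.
#' @param axis A `flim_time_axis`.
#' @param oversample Convolution oversampling passed to [synthesize_clean()].
#' @return An object of class `flim_dataset_spec`.
#' @export
dataset_spec <- function(n_signals, seed,
                         mono_fraction = 0.5,
                         mono_tau_range = c(0.1, 5),
                         bi_tau1_range = c(0.1, 1),
                         bi_tau2_range = c(1, 5),
                         snr_range_db = c(20, 40),
                         irf_fwhm_mean = 167,
                         irf_fwhm_sd = 60,
                         irf_fwhm_floor = 20,
                         axis = time_axis(),
                         oversample = 4L) {
  n_signals <- as.integer(n_signals)
  if (is.na(n_signals) || n_signals < 1L)
    stop("`n_signals` must be a positive integer")
  if (length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer")
  if (!is.finite(mono_fraction) || mono_fraction < 0 || mono_fraction > 1)
    stop("`mono_fraction` must lie in [0, 1]")
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] <= 0 || r[2] < r[1])
      stop(sprintf("`%s` must be a valid positive interval", nm))
  }
  chk_range(mono_tau_range, "mono_tau_range")
  chk_range(bi_tau1_range, "bi_tau1_range")
  chk_range(bi_tau2_range, "bi_tau2_range")
  if (length(snr_range_db) != 2L || any(!is.finite(snr_range_db)) ||
      snr_range_db[2] < snr_range_db[1])
    stop("`snr_range_db` must be a valid interval")
  if (irf_fwhm_mean <= 0 || irf_fwhm_sd < 0 || irf_fwhm_floor <= 0)
    stop("IRF FWHM parameters must be positive")
  structure(list(
    n_signals = n_signals, seed = as.integer(seed),
    mono_fraction = mono_fraction,
    mono_tau_range = mono_tau_range,
    bi_tau1_range = bi_tau1_range, bi_tau2_range = bi_tau2_range,
    snr_range_db = snr_range_db,
    irf_fwhm_mean = irf_fwhm_mean, irf_fwhm_sd = irf_fwhm_sd,
    irf_fwhm_floor = irf_fwhm_floor,
    axis = axis, oversample = as.integer(oversample)
  ), class = "flim_dataset_spec")
}

#' Generate a simulated (histogram, lifetime) dataset
#'
#' Draws per-signal decay parameters, IRF width, and photon budget according
#' to a [dataset_spec()], synthesizes each clean curve, applies Poisson
#' noise, and labels each histogram with its amplitude-weighted average
#' lifetime. Fully reproducible: the same spec (including seed) yields a
#' bitwise-identical dataset.
#'
#' @param spec A `flim_dataset_spec`.
#' @return An object of class `flim_dataset`: a list with `histograms`
#'   (n_signals x n_bins integer matrix), `labels` (tau_A in ns), `params`
#'   (data frame of per-signal ground truth: n_components, alpha1, tau1,
#'   tau2, fwhm_ps, snr_db, target_counts, total_counts), `axis`, `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "flim_dataset_spec"))
  axis <- spec$axis
  n <- spec$n_signals
  with_local_seed(spec$seed, {
    is_mono <- stats::runif(n) < spec$mono_fraction
    tau1 <- ifelse(is_mono,
                   stats::runif(n, spec$mono_tau_range[1], spec$mono_tau_range[2]),
                   stats::runif(n, spec$bi_tau1_range[1], spec$bi_tau1_range[2]))
    tau2 <- ifelse(is_mono, NA_real_,
                   stats::runif(n, spec$bi_tau2_range[1], spec$bi_tau2_range[2]))
    alpha1 <- ifelse(is_mono, 1, stats::runif(n))
    fwhm <- pmax(spec$irf_fwhm_floor,
                 stats::rnorm(n, spec$irf_fwhm_mean, spec$irf_fwhm_sd))
    snr <- stats::runif(n, spec$snr_range_db[1], spec$snr_range_db[2])
    target <- counts_from_snr_db(snr)
    hists <- matrix(0L, nrow = n, ncol = axis$n_bins)
    labels <- numeric(n)
    for (i in seq_len(n)) {
      model <- if (is_mono[i]) decay_model(1, tau1[i]) else
        decay_model(c(alpha1[i], 1 - alpha1[i]), c(tau1[i], tau2[i]))
      clean <- synthesize_clean(model, irf_spec(fwhm[i]), axis,
                                oversample = spec$oversample)
      lam <- clean * (target[i] / sum(clean))
      hists[i, ] <- stats::rpois(axis$n_bins, lam)
      labels[i] <- amplitude_weighted_lifetime(model)
    }
    params <- data.frame(
      n_components = ifelse(is_mono, 1L, 2L),
      alpha1 = alpha1, tau1 = tau1, tau2 = tau2,
      fwhm_ps = fwhm, snr_db = snr,
      target_counts = target, total_counts = rowSums(hists)
    )
    structure(list(histograms = hists, labels = labels, params = params,
                   axis = axis, spec = spec),
              class = "flim_dataset")
  })
}

#' Write / read a simulated dataset as CSV + JSON
#'
#' Plain-text serialization: `<prefix>_histograms.csv` (counts, one row per
#' signal), `<prefix>_params.csv` (ground-truth manifest incl. the tau_A
#' label), and `<prefix>_meta.json` (axis and generating ranges).
#'
#' @param dataset A `flim_dataset`.
#' @param prefix Output path prefix.
#' @return `write_dataset()` returns the three file paths invisibly;
#'   `read_dataset()` returns a `flim_dataset` (with `spec = NULL`).
#' @export
write_dataset <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "flim_dataset"))
  paths <- paste0(prefix, c("_histograms.csv", "_params.csv", "_meta.json"))
  utils::write.table(dataset$histograms, paths[1], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  manifest <- cbind(dataset$params, tau_a = dataset$labels)
  utils::write.csv(manifest, paths[2], row.names = FALSE)
  sp <- dataset$spec
  meta <- list(n_bins = dataset$axis$n_bins, bin_width = dataset$axis$bin_width,
               n_signals = nrow(dataset$histograms))
  if (!is.null(sp))
    meta <- c(meta, list(seed = sp$seed, mono_fraction = sp$mono_fraction,
                         mono_tau_range = sp$mono_tau_range,
                         bi_tau1_range = sp$bi_tau1_range,
                         bi_tau2_range = sp$bi_tau2_range,
                         snr_range_db = sp$snr_range_db))
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_dataset
#' @param prefix Path prefix used when writing.
#' @export
read_dataset <- function(prefix) {
  paths <- paste0(prefix, c("_histograms.csv", "_params.csv", "_meta.json"))
  for (p in paths) if (!file.exists(p))
    stop(sprintf("missing dataset file '%s'", p))
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  axis <- time_axis(meta$n_bins, meta$bin_width)
  hists <- as.matrix(utils::read.table(paths[1], sep = ","))
  dimnames(hists) <- NULL
  storage.mode(hists) <- "integer"
  manifest <- utils::read.csv(paths[2])
  structure(list(histograms = hists, labels = manifest$tau_a,
                 params = manifest[setdiff(names(manifest), "tau_a")],
                 axis = axis, spec = NULL),
            class = "flim_dataset")
}
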