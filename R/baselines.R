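# Classical curve-fitting estimators of the amplitude-weighted lifetime.
# All share the simulator's forward model: a unit-amplitude exponential
# (per component) convolved with the Gaussian IRF on an oversampled grid
# and re-binned, with a free overall amplitude.

# Returns f(tau_vec) -> n_bins x length(tau_vec) matrix of unit-amplitude
# convolved decay curves; the IRF kernel FFT is precomputed once.
decay_projector <- function(irf, axis, oversample = 4L) {
  n_os <- axis$n_bins * as.integer(oversample)
  dt <- axis$bin_width / oversample
  t_os <- (seq_len(n_os) - 0.5) * dt
  k <- irf_kernel(irf, axis, t_os, dt)
  m <- stats::nextn(2L * n_os - 1L, 2)
  kf <- stats::fft(c(k, numeric(m - n_os)))
  os <- as.integer(oversample)
  function(tau) {
    vapply(tau, function(tt) {
      d <- exp(-t_os / tt)
      y <- Re(stats::fft(stats::fft(c(d, numeric(m - n_os))) * kf,
                         inverse = TRUE))[seq_len(n_os)] / m
      y[y < 0] <- 0
      colSums(matrix(y, nrow = os)) * dt
    }, numeric(axis$n_bins))
  }
}

# Canonicalize fitted components: order tau ascending, renormalize alpha.
canonical_fit <- function(alpha, tau) {
  o <- order(tau)
  alpha <- alpha[o]; tau <- tau[o]
  s <- sum(alpha)
  if (s > 0) alpha <- alpha / s
  list(alpha = alpha, tau = tau)
}

fit_result <- function(alpha, tau, converged, residual_norm, n_iterations,
                       method) {
  cf <- canonical_fit(alpha, tau)
  structure(list(alpha = cf$alpha, tau = cf$tau,
                 tau_a = sum(cf$alpha * cf$tau),
                 converged = converged, residual_norm = residual_norm,
                 n_iterations = n_iterations, method = method),
            class = "flim_fit_result")
}

check_fit_input <- function(histogram, n_components) {
  stopifnot(inherits(histogram, "flim_decay_histogram"))
  if (!n_components %in% c(1L, 2L))
    stop("`n_components` must be 1 or 2")
  if (histogram$total_counts < 10)
    stop("histogram is (near-)empty; cannot fit")
}

#' Center-of-mass lifetime estimate
#'
#' First temporal moment of the histogram relative to the decay start
#' `t0`: an intensity-weighted average lifetime. Fast and fit-free, but for
#' multiexponential decays it exceeds the amplitude-weighted average, and a
#' finite window truncates long tails (underestimating long lifetimes).
#'
#' @param histogram A `flim_decay_histogram`.
#' @param t0 Decay start time in ns (e.g. the IRF peak position).
#' @return Intensity-weighted lifetime in ns.
#' @export
fit_cmm <- function(histogram, t0 = 0) {
  stopifnot(inherits(histogram, "flim_decay_histogram"))
  if (histogram$total_counts <= 0) stop("histogram has no counts")
  tt <- axis_times(histogram$axis)
  sum(tt * histogram$counts) / histogram$total_counts - t0
}

#' Nonlinear least-squares (NLSM) decay fit
#'
#' Levenberg-Marquardt minimization of the unweighted squared residual
#' between the IRF-convolved multiexponential model and the measured
#' counts, over amplitude, fractions, and lifetimes (bounds: tau in
#' `[0.01, 20]` ns, alpha in `[0, 1]`). Initial lifetimes derive from the
#' center-of-mass estimate, so no manual initialization is needed.
#'
#' @param histogram A `flim_decay_histogram`.
#' @param irf The `flim_irf` of the acquisition.
#' @param n_components 1 (mono) or 2 (biexponential).
#' @param init Optional named list overriding the automatic initialization
#'   (`tau`, and for `n_components = 2` also `alpha1`).
#' @param oversample Forward-model oversampling (matches the simulator).
#' @return A `flim_fit_result` with fields `alpha`, `tau` (ordered
#'   ascending), `tau_a`, `converged`, `residual_norm`, `n_iterations`.
#' @export
fit_nlsm <- function(histogram, irf, n_components = 1L, init = NULL,
                     oversample = 4L) {
  check_fit_input(histogram, n_components)
  axis <- histogram$axis
  y <- as.numeric(histogram$counts)
  proj <- decay_projector(irf, axis, oversample)
  t0 <- irf_t0(irf, axis)
  cmm <- min(max(fit_cmm(histogram, t0), 0.05), 10)
  lo_tau <- 0.01; hi_tau <- 20
  if (n_components == 1L) {
    tau0 <- if (!is.null(init$tau)) init$tau else cmm
    a0 <- histogram$total_counts / sum(proj(tau0))
    resid_fn <- function(p) p[1] * drop(proj(p[2])) - y
    fit <- minpack.lm::nls.lm(
      par = c(a0, tau0), fn = resid_fn,
      lower = c(0, lo_tau), upper = c(Inf, hi_tau),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-8))
    fit_result(1, fit$par[2], fit$info %in% 1:3, fit$deviance, fit$niter,
               "nlsm")
  } else {
    tau0 <- if (!is.null(init$tau)) init$tau else
      pmin(pmax(c(0.5, 1.5) * cmm, lo_tau * 2), hi_tau / 2)
    al0 <- if (!is.null(init$alpha1)) init$alpha1 else 0.5
    a0 <- histogram$total_counts / sum(proj(tau0[1]))
    resid_fn <- function(p) {
      D <- proj(p[3:4])
      p[1] * drop(D %*% c(p[2], 1 - p[2])) - y
    }
    fit <- minpack.lm::nls.lm(
      par = c(a0, al0, tau0),
      fn = resid_fn,
      lower = c(0, 0, lo_tau, lo_tau), upper = c(Inf, 1, hi_tau, hi_tau),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-8))
    p <- fit$par
    fit_result(c(p[2], 1 - p[2]), p[3:4], fit$info %in% 1:3,
               fit$deviance, fit$niter, "nlsm")
  }
}

# Non-negative amplitude solve for a design matrix of decay columns;
# ridge-regularized when the columns are (near-)collinear.
solve_amplitudes <- function(D, y) {
  if (ncol(D) > 1L) {
    sv <- svd(D, nu = 0, nv = 0)$d
    if (sv[length(sv)] <= 1e-8 * sv[1]) {
      warning("near-singular design (tau values coincide); using a regularized solve")
      G <- crossprod(D) + diag(1e-8 * sv[1]^2, ncol(D))
      c0 <- solve(G, crossprod(D, y))
      return(pmax(drop(c0), 0))
    }
  }
  drop(pracma::lsqnonneg(D, y)$x)
}

#' Variable-projection (VPM) decay fit
#'
#' VarPro fit of the same objective as [fit_nlsm()]: the nonlinear search
#' runs over the lifetimes only, while the linear amplitudes are solved in
#' closed form (non-negative least squares) at every candidate. This
#' removes the amplitude dimensions from the search and needs no amplitude
#' initialization.
#'
#' @inheritParams fit_nlsm
#' @return A `flim_fit_result`.
#' @export
fit_vpm <- function(histogram, irf, n_components = 1L, oversample = 4L) {
  check_fit_input(histogram, n_components)
  axis <- histogram$axis
  y <- as.numeric(histogram$counts)
  proj <- decay_projector(irf, axis, oversample)
  t0 <- irf_t0(irf, axis)
  cmm <- min(max(fit_cmm(histogram, t0), 0.05), 10)
  lo_tau <- 0.01; hi_tau <- 20
  objective <- function(tau) {
    D <- proj(tau)
    cc <- solve_amplitudes(D, y)
    r <- y - drop(D %*% cc)
    sum(r * r)
  }
  if (n_components == 1L) {
    opt <- stats::optimize(objective, interval = c(lo_tau, hi_tau),
                           tol = 1e-6)
    tau_hat <- opt$minimum
    it <- NA_integer_; conv <- TRUE; obj <- opt$objective
  } else {
    start <- pmin(pmax(c(0.5, 1.5) * cmm, lo_tau * 2), hi_tau / 2)
    opt <- stats::nlminb(start, objective, lower = lo_tau, upper = hi_tau,
                         control = list(iter.max = 500, rel.tol = 1e-8))
    tau_hat <- opt$par
    it <- opt$iterations; conv <- opt$convergence == 0; obj <- opt$objective
  }
  cc <- solve_amplitudes(proj(tau_hat), y)
  if (sum(cc) <= 0) cc <- rep(1, length(tau_hat))
  fit_result(cc / sum(cc), tau_hat, conv, obj, it, "vpm")
}
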