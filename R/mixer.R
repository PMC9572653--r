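#' MLP-Mixer configuration
#'
#' Hyperparameters of the mixer regressor. Defaults follow the compact
#' configuration used throughout this package: patch size 10, one mixer
#' block, token and channel dimensions of 16, and a three-layer dense
#' regression head (64, 32, 1).
#'
#' @param patch_size Time bins per non-overlapping patch.
#' @param n_blocks Number of mixer blocks.
#' @param channel_dim Per-patch embedding width (channels).
#' @param token_hidden Hidden width of the token-mixing MLP.
#' @param channel_hidden Hidden width of the channel-mixing MLP.
#' @param dropout_rate Dropout applied inside the mixer MLPs during
#'   training; disabled at inference.
#' @param head_widths Hidden widths of the dense regression head; a final
#'   linear layer to one scalar output is appended automatically, so the
#'   default `c(64, 32)` yields the three dense layers 64 -> 32 -> 1.
#' @return An object of class `mixer_config`.
#' @export
mixer_config <- function(patch_size = 10L, n_blocks = 1L, channel_dim = 16L,
                         token_hidden = 16L, channel_hidden = 16L,
                         dropout_rate = 0.1, head_widths = c(64L, 32L)) {
  ints <- c(patch_size = patch_size, n_blocks = n_blocks,
            channel_dim = channel_dim, token_hidden = token_hidden,
            channel_hidden = channel_hidden)
  if (any(!is.finite(ints)) || any(ints < 1) || any(ints != round(ints)))
    stop("patch_size, n_blocks, channel_dim, token_hidden and channel_hidden must be positive integers")
  if (!is.finite(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)")
  if (length(head_widths) < 1L || any(!is.finite(head_widths)) ||
      any(head_widths < 1) || any(head_widths != round(head_widths)))
    stop("`head_widths` must contain at least one positive integer (the regression head needs at least one dense layer before the output)")
  structure(list(patch_size = as.integer(patch_size),
                 n_blocks = as.integer(n_blocks),
                 channel_dim = as.integer(channel_dim),
                 token_hidden = as.integer(token_hidden),
                 channel_hidden = as.integer(channel_hidden),
                 dropout_rate = dropout_rate,
                 head_widths = as.integer(head_widths)),
            class = "mixer_config")
}

#' Split a histogram into non-overlapping patches
#'
#' Zero-pads the vector to the next multiple of `patch_size` (padding falls
#' in the low-signal tail) and reshapes it into contiguous patches.
#' Concatenating the rows of the result and trimming the padding recovers
#' the input exactly.
#'
#' @param x Numeric vector (one histogram).
#' @param patch_size Bins per patch (positive integer).
#' @return An `n_patches x patch_size` matrix.
#' @export
#' @examples
#' dim(patchify(numeric(256), 10))  # 26 x 10, last patch carries 4 zeros
patchify <- function(x, patch_size) {
  patch_size <- as.integer(patch_size)
  if (is.na(patch_size) || patch_size < 1L)
    stop("`patch_size` must be a positive integer")
  if (length(x) < 1L) stop("`x` must be non-empty")
  n_p <- ceiling(length(x) / patch_size)
  padded <- c(x, numeric(n_p * patch_size - length(x)))
  matrix(padded, nrow = n_p, ncol = patch_size, byrow = TRUE)
}

# Fan-in uniform initialization (U(-1/sqrt(fan_in), 1/sqrt(fan_in))) for a
# dense layer, matching common deep-learning defaults.
init_dense <- function(fan_in, fan_out) {
  b <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -b, b), fan_in, fan_out),
       b = stats::runif(fan_out, -b, b))
}

#' Construct an MLP-Mixer lifetime regressor
#'
#' Builds the network: per-patch linear embedding, `n_blocks` mixer blocks
#' (layer norm, token-mixing MLP across patches, layer norm, channel-mixing
#' MLP across channels, GELU nonlinearities, skip connections around both
#' MLPs), then a dense regression head ending in one scalar: the
#' amplitude-weighted average lifetime in ns.
#'
#' @param config A [mixer_config()].
#' @param input_length Histogram length the network accepts (bins before
#'   padding; inputs are zero-padded to a multiple of the patch size).
#' @param seed Optional seed for reproducible weight initialization.
#' @return An object of class `mixer_network`.
#' @export
mixer_network <- function(config = mixer_config(), input_length = 256L,
                          seed = NULL) {
  stopifnot(inherits(config, "mixer_config"))
  input_length <- as.integer(input_length)
  if (is.na(input_length) || input_length < config$patch_size)
    stop("`input_length` must be at least one patch long")
  n_p <- as.integer(ceiling(input_length / config$patch_size))
  padded <- n_p * config$patch_size
  C <- config$channel_dim
  params <- with_local_seed(seed, {
    p <- list(embed = init_dense(config$patch_size, C))
    for (b in seq_len(config$n_blocks)) {
      p[[paste0("block", b)]] <- list(
        ln1_g = rep(1, C), ln1_b = rep(0, C),
        tok1 = init_dense(n_p, config$token_hidden),
        tok2 = init_dense(config$token_hidden, n_p),
        ln2_g = rep(1, C), ln2_b = rep(0, C),
        ch1 = init_dense(C, config$channel_hidden),
        ch2 = init_dense(config$channel_hidden, C)
      )
    }
    widths <- c(n_p * C, config$head_widths, 1L)
    p$head <- stats::setNames(
      lapply(seq_len(length(widths) - 1L), function(i)
        init_dense(widths[i], widths[i + 1L])),
      paste0("fc", seq_len(length(widths) - 1L)))
    p
  })
  structure(list(config = config, input_length = input_length,
                 padded_length = padded, n_patches = n_p, params = params),
            class = "mixer_network")
}

#' Count trainable parameters
#'
#' @param network A `mixer_network`.
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(network) {
  stopifnot(inherits(network, "mixer_network"))
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(network$params)
  n
}

# GELU in its sigmoid form, gelu(x) = x * sigmoid(1.702 x); the cached
# sigmoid makes the backward pass free of transcendental calls.
gelu_sig <- function(x) 1 / (1 + exp(-1.702 * x))
gelu_grad_s <- function(x, s) s * (1 + 1.702 * x * (1 - s))

# Layer norm across columns (channels) per row, with affine (g, b).
ln_fwd <- function(x, g, b, eps = 1e-6) {
  n <- nrow(x); k <- ncol(x)
  mu <- .rowMeans(x, n, k)
  xc <- x - mu
  inv <- 1 / sqrt(.rowMeans(xc * xc, n, k) + eps)
  xhat <- xc * inv
  list(out = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dy); k <- ncol(dy)
  dg <- .colSums(dy * xhat, n, k)
  db <- .colSums(dy, n, k)
  dxh <- dy * rep(g, each = n)
  dx <- cache$inv *
    (dxh - .rowMeans(dxh, n, k) - xhat * .rowMeans(dxh * xhat, n, k))
  list(dx = dx, dg = dg, db = db)
}

drop_mask <- function(nr, nc, rate) {
  matrix((stats::runif(nr * nc) >= rate) / (1 - rate), nr, nc)
}

# (n_p*B) x C  <->  (C*B) x n_p  reorderings used around the token MLP.
to_tokens <- function(E, n_p, B, C) {
  matrix(aperm(array(E, c(n_p, B, C)), c(3L, 2L, 1L)), nrow = C * B)
}
from_tokens <- function(T_, n_p, B, C) {
  matrix(aperm(array(T_, c(C, B, n_p)), c(3L, 2L, 1L)), nrow = n_p * B)
}

add_bias <- function(x, b) x + rep(b, each = nrow(x))

# Core forward pass. `x` is a B x input_length matrix of normalized
# histograms. Returns predictions; with cache = TRUE also every
# intermediate needed for backprop. Dropout masks are drawn from the
# caller's RNG stream when training = TRUE.
mixer_fwd <- function(network, x, training = FALSE, cache = FALSE) {
  cfg <- network$config
  P <- cfg$patch_size; n_p <- network$n_patches; C <- cfg$channel_dim
  B <- nrow(x)
  pad <- network$padded_length - ncol(x)
  if (pad > 0) x <- cbind(x, matrix(0, B, pad))
  # patches: P x (n_p*B), columns ordered patch-fastest then sample
  Pm <- matrix(t(x), nrow = P)
  pr <- network$params
  E <- add_bias(crossprod(Pm, pr$embed$W), pr$embed$b)  # (n_p*B) x C
  drop_rate <- if (training) cfg$dropout_rate else 0
  blocks <- vector("list", cfg$n_blocks)
  for (bi in seq_len(cfg$n_blocks)) {
    bp <- pr[[paste0("block", bi)]]
    ln1 <- ln_fwd(E, bp$ln1_g, bp$ln1_b)
    Tm <- to_tokens(ln1$out, n_p, B, C)                  # (C*B) x n_p
    pre1 <- add_bias(Tm %*% bp$tok1$W, bp$tok1$b)
    s1 <- gelu_sig(pre1)
    H1 <- pre1 * s1
    m1 <- if (drop_rate > 0) drop_mask(nrow(H1), ncol(H1), drop_rate) else NULL
    H1d <- if (is.null(m1)) H1 else H1 * m1
    O1 <- add_bias(H1d %*% bp$tok2$W, bp$tok2$b)         # (C*B) x n_p
    E1 <- E + from_tokens(O1, n_p, B, C)                 # skip
    ln2 <- ln_fwd(E1, bp$ln2_g, bp$ln2_b)
    pre2 <- add_bias(ln2$out %*% bp$ch1$W, bp$ch1$b)
    s2 <- gelu_sig(pre2)
    H2 <- pre2 * s2
    m2 <- if (drop_rate > 0) drop_mask(nrow(H2), ncol(H2), drop_rate) else NULL
    H2d <- if (is.null(m2)) H2 else H2 * m2
    O2 <- add_bias(H2d %*% bp$ch2$W, bp$ch2$b)
    E2 <- E1 + O2                                        # skip
    if (cache)
      blocks[[bi]] <- list(E = E, ln1 = ln1, Tm = Tm, pre1 = pre1, s1 = s1,
                           m1 = m1, H1d = H1d, E1 = E1, ln2 = ln2,
                           pre2 = pre2, s2 = s2, m2 = m2, H2d = H2d)
    E <- E2
  }
  # flatten per sample (patch-fastest within channel), B x (n_p*C)
  Fm <- t(matrix(aperm(array(E, c(n_p, B, C)), c(1L, 3L, 2L)),
                 nrow = n_p * C))
  hs <- vector("list", length(pr$head))
  a <- Fm
  n_head <- length(pr$head)
  for (i in seq_len(n_head)) {
    pre <- add_bias(a %*% pr$head[[i]]$W, pr$head[[i]]$b)
    s <- if (i < n_head) gelu_sig(pre) else NULL
    out <- if (i < n_head) pre * s else pre
    if (cache) hs[[i]] <- list(input = a, pre = pre, s = s)
    a <- out
  }
  y <- drop(a)
  if (!cache) return(y)
  list(y = y, Fm = Fm, blocks = blocks, head = hs, Pm = Pm, B = B)
}

# Backward pass: gradient of sum(dy * y) w.r.t. every parameter.
mixer_bwd <- function(network, cache, dy) {
  cfg <- network$config
  n_p <- network$n_patches; C <- cfg$channel_dim
  B <- cache$B
  pr <- network$params
  g <- list()
  # head
  da <- matrix(dy, ncol = 1L)
  n_head <- length(pr$head)
  g$head <- stats::setNames(vector("list", n_head), names(pr$head))
  for (i in rev(seq_len(n_head))) {
    hc <- cache$head[[i]]
    dpre <- if (i < n_head) da * gelu_grad_s(hc$pre, hc$s) else da
    g$head[[i]] <- list(W = crossprod(hc$input, dpre), b = colSums(dpre))
    da <- dpre %*% t(pr$head[[i]]$W)
  }
  # un-flatten
  dE <- matrix(aperm(array(t(da), c(n_p, C, B)), c(1L, 3L, 2L)),
               nrow = n_p * B)
  for (bi in rev(seq_len(cfg$n_blocks))) {
    bp <- pr[[paste0("block", bi)]]
    bc <- cache$blocks[[bi]]
    gb <- list()
    # channel-mixing: E2 = E1 + O2
    dO2 <- dE
    dH2d <- dO2 %*% t(bp$ch2$W)
    gb$ch2 <- list(W = crossprod(bc$H2d, dO2), b = colSums(dO2))
    dH2 <- if (is.null(bc$m2)) dH2d else dH2d * bc$m2
    dpre2 <- dH2 * gelu_grad_s(bc$pre2, bc$s2)
    gb$ch1 <- list(W = crossprod(bc$ln2$out, dpre2), b = colSums(dpre2))
    dV <- dpre2 %*% t(bp$ch1$W)
    l2 <- ln_bwd(dV, bc$ln2, bp$ln2_g)
    gb$ln2_g <- l2$dg; gb$ln2_b <- l2$db
    dE1 <- dE + l2$dx
    # token-mixing: E1 = E + from_tokens(O1)
    dO1 <- to_tokens(dE1, n_p, B, C)
    dH1d <- dO1 %*% t(bp$tok2$W)
    gb$tok2 <- list(W = crossprod(bc$H1d, dO1), b = colSums(dO1))
    dH1 <- if (is.null(bc$m1)) dH1d else dH1d * bc$m1
    dpre1 <- dH1 * gelu_grad_s(bc$pre1, bc$s1)
    gb$tok1 <- list(W = crossprod(bc$Tm, dpre1), b = colSums(dpre1))
    dTm <- dpre1 %*% t(bp$tok1$W)
    dU <- from_tokens(dTm, n_p, B, C)
    l1 <- ln_bwd(dU, bc$ln1, bp$ln1_g)
    gb$ln1_g <- l1$dg; gb$ln1_b <- l1$db
    dE <- dE1 + l1$dx
    g[[paste0("block", bi)]] <- gb
  }
  g$embed <- list(W = cache$Pm %*% dE, b = colSums(dE))
  g
}

#' Forward pass: predict lifetimes from normalized histograms
#'
#' Runs the network in inference mode (dropout disabled; deterministic).
#' Inputs must already follow the training normalization (peak scaled
#' to 1); see [normalize_histogram()]. Inputs shorter than the padded
#' length are zero-padded on the right.
#'
#' @param network A `mixer_network`.
#' @param x A numeric vector (one histogram) or a B x L matrix of
#'   normalized histograms with `L = network$input_length`.
#' @param engine `"cpp"` (compiled batch kernels, default) or `"r"` (pure-R
#'   reference implementation); both compute the same function and are
#'   cross-checked in the test suite.
#' @return Numeric vector of B predicted amplitude-weighted lifetimes (ns).
#' @export
mixer_forward <- function(network, x, engine = c("cpp", "r")) {
  stopifnot(inherits(network, "mixer_network"))
  engine <- match.arg(engine)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != network$input_length && ncol(x) != network$padded_length)
    stop(sprintf("input length %d does not match the network's expected %d bins",
                 ncol(x), network$input_length))
  if (engine == "r")
    return(mixer_fwd(network, x, training = FALSE, cache = FALSE))
  pad <- network$padded_length - ncol(x)
  if (pad > 0) x <- cbind(x, matrix(0, nrow(x), pad))
  cfg <- network$config
  drop(.mixer_infer_cpp(network$params, x, cfg$patch_size, network$n_patches,
                        cfg$channel_dim, cfg$n_blocks))
}

# Flatten/unflatten parameter pytrees for the optimizer.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[nm]])) out <- c(out, flatten_params(p[[nm]], key))
    else out[[key]] <- p[[nm]]
  }
  out
}

assign_flat <- function(p, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    p <- modify_path(p, path, flat[[key]])
  }
  p
}

modify_path <- function(p, path, value) {
  if (length(path) == 1L) p[[path]] <- value
  else p[[path[1]]] <- modify_path(p[[path[1]]], path[-1], value)
  p
}
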