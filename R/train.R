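#' Peak-normalize a decay histogram
#'
#' Divides by the maximum bin value so the peak equals 1 — the convention
#' used for every histogram fed to the network, at training and at
#' inference. Order-preserving, idempotent, and invariant to rescaling the
#' counts.
#'
#' @param counts Non-negative numeric vector (or a `flim_decay_histogram`).
#' @return Numeric vector with maximum 1.
#' @export
#' @examples
#' normalize_histogram(c(0, 5, 10, 2))
normalize_histogram <- function(counts) {
  if (inherits(counts, "flim_decay_histogram")) counts <- counts$counts
  if (length(counts) < 1L || any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be non-negative and finite")
  m <- max(counts)
  if (m <= 0) stop("cannot normalize an all-zero histogram")
  counts / m
}

# Row-wise peak normalization of a histogram matrix.
normalize_rows <- function(h) {
  m <- apply(h, 1L, max)
  if (any(m <= 0)) stop("cannot normalize an all-zero histogram")
  h / m
}

#' Mean squared error loss
#'
#' @param predictions,labels Equal-length numeric vectors.
#' @return Mean over the batch of squared differences.
#' @export
mse_loss <- function(predictions, labels) {
  if (length(predictions) != length(labels) || length(labels) < 1L)
    stop("`predictions` and `labels` must be non-empty and of equal length")
  mean((predictions - labels)^2)
}

#' Training configuration
#'
#' Optimization protocol for the mixer: Adam at learning rate 1e-4, batch
#' size 200, 20% validation split, early stopping with patience 20 epochs.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of the dataset held out for validation.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param max_epochs Hard cap on epochs.
#' @param seed RNG seed covering the split, shuffling, weight init (when the
#'   network is built inside [train_mixer()]) and dropout.
#' @return An object of class `mixer_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 200L,
                         val_fraction = 0.2, early_stop_patience = 20L,
                         max_epochs = 500L, seed = 1L) {
  if (!is.finite(learning_rate) || learning_rate <= 0)
    stop("`learning_rate` must be positive")
  if (!is.finite(batch_size) || batch_size < 1)
    stop("`batch_size` must be >= 1")
  if (!is.finite(val_fraction) || val_fraction <= 0 || val_fraction >= 1)
    stop("`val_fraction` must lie in (0, 1)")
  if (!is.finite(early_stop_patience) || early_stop_patience < 1)
    stop("`early_stop_patience` must be >= 1")
  if (!is.finite(max_epochs) || max_epochs < 1)
    stop("`max_epochs` must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "mixer_train_config")
}

# One Adam update over flattened parameter lists keyed by name.
adam_step <- function(flat, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in names(flat)) {
    gk <- grad[[k]]
    if (is.matrix(gk) && !is.matrix(flat[[k]])) gk <- as.numeric(gk)
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk * gk
    flat[[k]] <- flat[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(flat = flat, state = state)
}

# Chunked inference-mode MSE (avoids one giant matrix product).
eval_mse <- function(network, x, y, chunk = 1000L) {
  n <- nrow(x)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  sq <- 0
  for (ii in idx) {
    p <- mixer_forward(network, x[ii, , drop = FALSE])
    sq <- sq + sum((p - y[ii])^2)
  }
  sq / n
}

#' Train the mixer on a simulated dataset
#'
#' Minimizes the mean squared error between predicted and true
#' amplitude-weighted lifetimes with Adam, stopping early when the
#' validation MSE has not improved for `early_stop_patience` epochs, and
#' returning the weights of the best validation epoch. The validation split
#' is a seeded shuffle, stratified by decay order (mono/bi) when the
#' dataset carries per-signal parameters. Histograms are peak-normalized
#' internally. Fully reproducible for a fixed `config$seed`.
#'
#' @param dataset A `flim_dataset` (from [generate_dataset()] or
#'   [read_dataset()]), or a list with `histograms` and `labels`.
#' @param config A [train_config()].
#' @param network Optional pre-built [mixer_network()]; by default one is
#'   constructed for the dataset's histogram length with weights seeded
#'   from `config$seed`.
#' @param engine `"cpp"` (compiled batch kernels, default) or `"r"`
#'   (pure-R reference path).
#' @param verbose Print per-epoch losses to stderr.
#' @return A list of class `mixer_fit`: `network` (best weights), `history`
#'   (data frame with `epoch`, `train_mse`, `val_mse`), `best_epoch`,
#'   `best_val_mse`, `stopped_early`.
#' @export
train_mixer <- function(dataset, config = train_config(), network = NULL,
                        engine = c("cpp", "r"), verbose = FALSE) {
  stopifnot(inherits(config, "mixer_train_config"))
  engine <- match.arg(engine)
  h <- dataset$histograms
  y <- dataset$labels
  if (is.null(h) || is.null(y) || nrow(h) != length(y))
    stop("dataset must carry matching `histograms` and `labels`")
  n <- nrow(h)
  if (n < 2L) stop("dataset too small to split")
  x <- normalize_rows(h)
  strata <- if (!is.null(dataset$params$n_components))
    dataset$params$n_components else rep(1L, n)

  with_local_seed(config$seed, {
    if (is.null(network))
      network <- mixer_network(input_length = ncol(h))
    # stratified validation split
    val_idx <- unlist(lapply(split(seq_len(n), strata), function(ii) {
      k <- max(1L, round(config$val_fraction * length(ii)))
      sample(ii, k)
    }), use.names = FALSE)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(train_idx) < config$batch_size)
      stop("training split smaller than one batch; reduce `batch_size`")
    xv <- x[val_idx, , drop = FALSE]; yv <- y[val_idx]
    xt <- x[train_idx, , drop = FALSE]; yt <- y[train_idx]
    nt <- nrow(xt)

    flat <- flatten_params(network$params)
    zeros <- lapply(flat, function(p) p * 0)
    state <- list(t = 0L, m = zeros, v = zeros)
    best_val <- Inf; best_flat <- flat; best_epoch <- 0L
    tr_hist <- numeric(0); val_hist <- numeric(0)
    wait <- 0L; stopped <- FALSE

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nt)
      starts <- seq(1L, nt, by = config$batch_size)
      ep_sq <- 0
      for (s in starts) {
        ii <- ord[s:min(s + config$batch_size - 1L, nt)]
        xb <- xt[ii, , drop = FALSE]; yb <- yt[ii]
        if (engine == "cpp") {
          cfg <- network$config
          pad <- network$padded_length - ncol(xb)
          xbp <- if (pad > 0) cbind(xb, matrix(0, nrow(xb), pad)) else xb
          step <- .mixer_step_cpp(network$params, xbp, yb, cfg$patch_size,
                                  network$n_patches, cfg$channel_dim,
                                  cfg$n_blocks, cfg$dropout_rate)
          err <- step$y - yb
          grad <- step$grads
        } else {
          cache <- mixer_fwd(network, xb, training = TRUE, cache = TRUE)
          err <- cache$y - yb
          grad <- mixer_bwd(network, cache, 2 * err / length(err))
        }
        if (any(!is.finite(err)))
          stop("training diverged: non-finite loss (check learning rate / data)")
        ep_sq <- ep_sq + sum(err^2)
        upd <- adam_step(flat, flatten_params(grad), state,
                         config$learning_rate)
        flat <- upd$flat; state <- upd$state
        network$params <- assign_flat(network$params, flat)
      }
      tr_hist[epoch] <- ep_sq / nt
      val_hist[epoch] <- eval_mse(network, xv, yv)
      if (verbose)
        message(sprintf("epoch %3d  train %.3e  val %.3e",
                        epoch, tr_hist[epoch], val_hist[epoch]))
      if (val_hist[epoch] < best_val) {
        best_val <- val_hist[epoch]; best_flat <- flat
        best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) { stopped <- TRUE; break }
      }
    }
    network$params <- assign_flat(network$params, best_flat)
    structure(list(
      network = network,
      history = data.frame(epoch = seq_along(tr_hist),
                           train_mse = tr_hist, val_mse = val_hist),
      best_epoch = best_epoch, best_val_mse = best_val,
      stopped_early = stopped,
      val_idx = sort(val_idx)
    ), class = "mixer_fit")
  })
}

#' Predict lifetimes from raw count histograms
#'
#' Convenience wrapper applying the training normalization before the
#' forward pass.
#'
#' @param network A trained `mixer_network`.
#' @param histograms Count vector or B x L matrix of raw counts.
#' @param clamp Clamp negative predictions to zero (reporting convention;
#'   default TRUE).
#' @return Predicted amplitude-weighted lifetimes (ns).
#' @export
predict_lifetime <- function(network, histograms, clamp = TRUE) {
  if (is.vector(histograms)) histograms <- matrix(histograms, nrow = 1L)
  p <- mixer_forward(network, normalize_rows(histograms))
  if (clamp) p <- pmax(p, 0)
  p
}

#' Save / load a model checkpoint
#'
#' Single-file JSON checkpoint carrying the configuration, input length,
#' normalization convention, and all weights; `load_checkpoint()`
#' reconstructs a numerically identical network.
#'
#' @param network A `mixer_network`.
#' @param path Checkpoint file path (.json).
#' @param meta Optional named list stored alongside (e.g. a training-data
#'   fingerprint).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns a `mixer_network`.
#' @export
save_checkpoint <- function(network, path, meta = list()) {
  stopifnot(inherits(network, "mixer_network"))
  flat <- flatten_params(network$params)
  obj <- list(
    format = "flimmixer-checkpoint-1",
    config = unclass(network$config),
    input_length = network$input_length,
    normalization = "peak-1",
    meta = meta,
    weights = lapply(flat, function(w)
      list(dim = if (is.matrix(w)) dim(w) else length(w), data = as.numeric(w)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "flimmixer-checkpoint-1")
    stop("not a flimmixer checkpoint: ", path)
  cfg <- do.call(mixer_config, obj$config)
  net <- mixer_network(cfg, input_length = obj$input_length)
  flat <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2]) else w$data
  })
  net$params <- assign_flat(net$params, flat)
  net
}
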