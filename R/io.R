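#' FLIM histogram image stack
#'
#' An H x W x T array of per-pixel TCSPC histograms with its time axis.
#'
#' @param data Non-negative integer array, dimensions H x W x T with
#'   `T = axis$n_bins`.
#' @param axis A `flim_time_axis`.
#' @param metadata Free-form named list of acquisition annotations.
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(data, axis, metadata = list()) {
  stopifnot(inherits(axis, "flim_time_axis"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (H x W x T)")
  if (dim(data)[3] != axis$n_bins)
    stop("third dimension must equal `axis$n_bins`")
  if (any(!is.finite(data)) || any(data < 0))
    stop("counts must be non-negative and finite")
  structure(list(data = data, axis = axis, metadata = metadata),
            class = "flim_stack")
}

stack_sidecar <- function(path) paste0(path, ".json")

#' Write / read a FLIM stack as multipage TIFF + JSON sidecar
#'
#' The stack is stored as T pages of H x W 32-bit frames holding
#' `counts / 2^24` (TIFF samples are quantized on `[0, 1]`; the power-of-two
#' scale, recorded in the sidecar, makes the integer round trip exact for
#' any realistic photon count) with a JSON sidecar `<path>.json` carrying
#' `n_bins`, `bin_width`, the scale, and metadata.
#'
#' @param stack A `flim_stack`.
#' @param path TIFF file path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()` returns
#'   a `flim_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  scale <- 2^24
  if (max(stack$data) >= scale)
    stop("per-bin counts exceed the supported range (2^24)")
  pages <- lapply(seq_len(dim(stack$data)[3]),
                  function(t) stack$data[, , t] / scale)
  suppressWarnings(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE))
  jsonlite::write_json(
    list(n_bins = stack$axis$n_bins, bin_width = stack$axis$bin_width,
         count_scale = scale, metadata = stack$metadata),
    stack_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- stack_sidecar(path)
  if (!file.exists(sc))
    stop(sprintf(paste("missing time-axis sidecar '%s';",
                       "write a JSON file with fields n_bins and bin_width",
                       "next to the TIFF"), sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$n_bins) || is.null(meta$bin_width))
    stop(sprintf("sidecar '%s' must define n_bins and bin_width", sc))
  axis <- time_axis(meta$n_bins, meta$bin_width)
  scale <- if (is.null(meta$count_scale)) 2^24 else meta$count_scale
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != axis$n_bins)
    stop(sprintf("TIFF has %d pages but the sidecar declares %d bins",
                 length(pages), axis$n_bins))
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * scale
  if (any(abs(arr - round(arr)) > 0.4))
    warning("non-integer counts in TIFF; rounding to integers")
  arr <- round(arr)
  md <- meta$metadata
  flim_stack(arr, axis, if (is.null(md)) list() else as.list(md))
}

# Per-pixel total counts of a stack.
pixel_totals <- function(stack) {
  d <- dim(stack$data)
  matrix(rowSums(matrix(stack$data, d[1] * d[2], d[3])), d[1], d[2])
}

#' Mask low-count pixels
#'
#' A pixel is valid iff its total photon count is at least `fraction` times
#' the maximum per-pixel total in the image (default 10%), the scale-free
#' reading of an intensity threshold.
#'
#' @param stack A `flim_stack`.
#' @param fraction Threshold fraction in `[0, 1)`.
#' @return Logical H x W validity matrix.
#' @export
mask_low_counts <- function(stack, fraction = 0.1) {
  stopifnot(inherits(stack, "flim_stack"))
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1)
    stop("`fraction` must lie in [0, 1)")
  totals <- pixel_totals(stack)
  if (all(totals == 0)) stop("stack contains no photons")
  totals >= fraction * max(totals)
}

#' Per-pixel lifetime map
#'
#' @param tau_a H x W matrix of amplitude-weighted lifetimes (ns); finite
#'   wherever `mask` is `TRUE`.
#' @param mask Logical H x W validity matrix.
#' @param intensity H x W matrix of per-pixel total counts.
#' @return An object of class `flim_lifetime_map`.
#' @export
lifetime_map <- function(tau_a, mask, intensity) {
  if (!all(dim(tau_a) == dim(mask)) || !all(dim(tau_a) == dim(intensity)))
    stop("`tau_a`, `mask` and `intensity` must share dimensions")
  if (any(mask & !is.finite(tau_a)))
    stop("`tau_a` must be finite wherever `mask` is TRUE")
  structure(list(tau_a = tau_a, mask = mask, intensity = intensity),
            class = "flim_lifetime_map")
}

#' Per-pixel lifetime inference
#'
#' Peak-normalizes every valid pixel's histogram, batches the pixels
#' through the trained mixer, and assembles a [lifetime_map()]. Invalid
#' pixels are `NA` in the map (flagged by the mask, never zero-filled).
#' Input counts are untouched and the intensity plane equals the per-pixel
#' sums exactly. Batching is a performance knob with no numerical effect.
#'
#' @param network A trained `mixer_network`.
#' @param stack A `flim_stack` with `axis$n_bins` matching the network's
#'   input length.
#' @param mask Optional logical validity matrix (default
#'   `mask_low_counts(stack)`).
#' @param batch_size Pixels per forward batch.
#' @return A `flim_lifetime_map`.
#' @export
predict_image <- function(network, stack, mask = NULL, batch_size = 1024L) {
  stopifnot(inherits(network, "mixer_network"), inherits(stack, "flim_stack"))
  if (stack$axis$n_bins != network$input_length)
    stop(sprintf("stack has %d time bins but the checkpoint expects %d",
                 stack$axis$n_bins, network$input_length))
  if (is.null(mask)) mask <- mask_low_counts(stack)
  d <- dim(stack$data)
  if (!all(dim(mask) == d[1:2])) stop("`mask` must be H x W")
  intensity <- pixel_totals(stack)
  tau <- matrix(NA_real_, d[1], d[2])
  idx <- which(mask)
  if (length(idx) > 0L) {
    pix <- matrix(stack$data, d[1] * d[2], d[3])[idx, , drop = FALSE]
    preds <- numeric(length(idx))
    starts <- seq(1L, length(idx), by = batch_size)
    for (s in starts) {
      ii <- s:min(s + batch_size - 1L, length(idx))
      preds[ii] <- predict_lifetime(network, pix[ii, , drop = FALSE])
    }
    tau[idx] <- preds
  }
  lifetime_map(tau, mask, intensity)
}

#' Write / read a lifetime map on disk
#'
#' Writes `<prefix>_tau.tif` (32-bit lifetimes stored as `tau / 64` with a
#' sentinel for masked pixels and a JSON sidecar recording the encoding;
#' [read_lifetime_map()] restores lifetimes to within ~1e-8 ns and masked
#' pixels as `NaN`), `<prefix>.png` (intensity-weighted color rendering),
#' and `<prefix>_summary.csv` (pixel counts and masked-region lifetime
#' statistics).
#'
#' @param map A `flim_lifetime_map`.
#' @param prefix Output path prefix.
#' @return The file paths, invisibly.
#' @export
write_lifetime_map <- function(map, prefix) {
  stopifnot(inherits(map, "flim_lifetime_map"))
  paths <- c(tif = paste0(prefix, "_tau.tif"),
             png = paste0(prefix, ".png"),
             csv = paste0(prefix, "_summary.csv"))
  scale <- 64
  if (any(map$tau_a[map$mask] < 0) || any(map$tau_a[map$mask] >= scale * 0.99))
    stop("lifetimes outside the encodable range [0, 63] ns")
  enc <- map$tau_a / scale
  enc[!map$mask] <- 1  # sentinel: masked
  suppressWarnings(
    tiff::writeTIFF(enc, paths["tif"], bits.per.sample = 32L, reduce = FALSE))
  jsonlite::write_json(list(tau_scale = scale, masked_sentinel = 1),
                       stack_sidecar(paths[["tif"]]),
                       auto_unbox = TRUE, digits = NA)
  # rendering: hue from lifetime, brightness from intensity
  tau <- map$tau_a
  v <- map$intensity / max(map$intensity, 1)
  tr <- if (any(map$mask)) range(tau[map$mask], finite = TRUE) else c(0, 1)
  span <- if (diff(tr) > 0) diff(tr) else 1
  hnorm <- (tau - tr[1]) / span
  hnorm[!map$mask] <- 0
  v[!map$mask] <- 0
  col <- grDevices::hsv(h = 0.7 * (1 - pmin(pmax(hnorm, 0), 1)), s = 1, v = v)
  rgb <- grDevices::col2rgb(col) / 255
  img <- array(0, c(nrow(tau), ncol(tau), 3L))
  img[, , 1] <- matrix(rgb[1, ], nrow(tau)); img[, , 2] <- matrix(rgb[2, ], nrow(tau))
  img[, , 3] <- matrix(rgb[3, ], nrow(tau))
  png::writePNG(img, paths["png"])
  valid <- map$tau_a[map$mask]
  utils::write.csv(data.frame(
    n_pixels = length(map$mask), n_masked = sum(!map$mask),
    mean_tau = mean(valid), median_tau = stats::median(valid)),
    paths["csv"], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_lifetime_map
#' @export
read_lifetime_map <- function(prefix) {
  tif <- paste0(prefix, "_tau.tif")
  sc <- stack_sidecar(tif)
  if (!file.exists(tif) || !file.exists(sc))
    stop("missing lifetime-map files under prefix ", prefix)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  enc <- tiff::readTIFF(tif)
  masked <- abs(enc - meta$masked_sentinel) < 1e-9
  tau <- enc * meta$tau_scale
  tau[masked] <- NaN
  list(tau_a = tau, mask = !masked)
}

#' Simulate a piecewise-constant FLIM phantom
#'
#' Builds an H x W x T stack whose left and right halves follow two
#' different decay models at a common photon budget — a quick end-to-end
#' test bed for per-pixel inference.
#'
#' @param models List of `flim_decay_model`, one per vertical stripe.
#' @param h,w Image height and width (w is split evenly across models).
#' @param counts Expected photons per pixel.
#' @param irf A `flim_irf`.
#' @param axis A `flim_time_axis`.
#' @param seed RNG seed.
#' @return A list: `stack` (`flim_stack`), `truth` (H x W matrix of true
#'   tau_A), `region` (H x W stripe index).
#' @export
simulate_phantom <- function(models, h = 16L, w = 16L, counts = 2500,
                             irf = irf_spec(), axis = time_axis(),
                             seed = 1L) {
  stopifnot(length(models) >= 1L)
  with_local_seed(seed, {
    nb <- axis$n_bins
    arr <- array(0L, c(h, w, nb))
    truth <- matrix(0, h, w)
    region <- matrix(0L, h, w)
    edges <- round(seq(0, w, length.out = length(models) + 1L))
    for (k in seq_along(models)) {
      cols <- (edges[k] + 1L):edges[k + 1L]
      clean <- synthesize_clean(models[[k]], irf, axis)
      lam <- clean * (counts / sum(clean))
      for (j in cols) for (i in seq_len(h))
        arr[i, j, ] <- stats::rpois(nb, lam)
      truth[, cols] <- amplitude_weighted_lifetime(models[[k]])
      region[, cols] <- k
    }
    list(stack = flim_stack(arr, axis), truth = truth, region = region)
  })
}
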