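#' Predict a whole-image plant probability map
#'
#' Full-resolution inference chain: intensities are scaled to `[0, 1]`, the
#' image is zero-padded to a 256-multiple, cut into non-overlapping 256x256
#' tiles, each tile is passed through the network, the per-tile probability
#' maps are reassembled, and the result is cropped back to the original
#' size.  Images smaller than one tile in either dimension are padded up
#' with a warning.
#'
#' @param model A trained `unet_model`.
#' @param image `H x W x 3` numeric array (0..255 or `[0, 1]`).
#' @param batch_size Tiles evaluated per forward pass (default 8).
#' @return `H x W` matrix of plant probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, image, batch_size = 8L) {
  stopifnot(inherits(model, "unet_model"))
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3L] != model$config$input_channels)
    stop("`image` must be an H x W x C array matching the model input channels")
  tile <- model$config$patch_size
  x <- normalize_intensities(image)
  p <- pad_to_tile_multiple(x, tile)
  grid <- extract_patches(p$image, p$pad_bottom, p$pad_right, tile)
  np <- length(grid$patches)
  probs <- vector("list", np)
  chunks <- split(seq_len(np), ceiling(seq_len(np) / batch_size))
  for (idx in chunks) {
    xb <- stack_patches(grid$patches[idx])
    pb <- unet_forward(model, xb, training = FALSE)$prob
    for (q in seq_along(idx))
      probs[[idx[q]]] <- pb[, , , q, drop = FALSE][, , , 1L, drop = FALSE]
  }
  pgrid <- grid
  pgrid$patches <- lapply(probs, function(a) array(a, dim = dim(a)[1:3]))
  pgrid$channels <- 1L
  reassemble(pgrid)
}

#' Threshold a probability map into a binary mask
#'
#' Pixels with probability greater than or equal to `threshold` become
#' plant (1), all others background (0).
#'
#' @param pmap `H x W` probability matrix in `[0, 1]`.
#' @param threshold Decision threshold, strictly inside (0, 1)
#'   (default 0.6).
#' @return Integer `H x W` mask with values in `{0, 1}`.
#' @export
threshold_probability <- function(pmap, threshold = 0.6) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly between 0 and 1")
  matrix(as.integer(pmap >= threshold), nrow(pmap), ncol(pmap))
}

#' Remove small connected components from a mask
#'
#' Labels plant components (8-connectivity by default, so diagonally
#' touching leaves and stems stay connected) and sets every component with
#' fewer than `min_size` pixels to background.  `min_size = 0` is the
#' identity; the operation is idempotent.
#'
#' @param mask Integer `H x W` binary mask.
#' @param min_size Minimum component size in pixels to keep.
#' @param connectivity 4 or 8 (default 8).
#' @return Cleaned integer `H x W` mask.
#' @export
remove_small_clusters <- function(mask, min_size, connectivity = 8L) {
  if (min_size < 0) stop("`min_size` must be non-negative")
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (min_size <= 1L || sum(m) == 0L) return(m)
  lab <- cpp_label_components(m, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_size)
  if (length(drop)) m[lab %in% drop] <- 0L
  m
}

#' Colorize a segmentation mask
#'
#' Returns an RGB image in which plant pixels keep their original colors
#' and background pixels are black.
#'
#' @param mask Integer `H x W` binary mask.
#' @param image `H x W x 3` RGB array aligned with the mask.
#' @return `H x W x 3` array of the same intensity scale as `image`.
#' @export
colorize <- function(mask, image) {
  d <- dim(image)
  if (length(d) != 3L || !identical(dim(mask), d[1:2]))
    stop("mask and image dimensions must match")
  image * array(rep(mask > 0, d[3L]), dim = d)
}

#' Segment a shoot image end to end
#'
#' Convenience chain: [predict_probability()], [threshold_probability()],
#' [remove_small_clusters()] and [colorize()].
#'
#' @param model A trained `unet_model`.
#' @param image `H x W x 3` RGB array.
#' @param threshold Probability threshold (default 0.6).
#' @param min_cluster_size Minimum kept component size in pixels; 0
#'   disables cleanup (default 0).
#' @param roi Optional `c(r0, c0, r1, c1)` rectangle (1-based, inclusive);
#'   pixels outside it are forced to background.
#' @return List with `probability` (matrix), `mask` (binary matrix) and
#'   `overlay` (RGB array).
#' @export
segment_image <- function(model, image, threshold = 0.6, min_cluster_size = 0L,
                          roi = NULL) {
  pmap <- predict_probability(model, image)
  mask <- threshold_probability(pmap, threshold)
  if (!is.null(roi)) {
    stopifnot(length(roi) == 4L)
    keep <- matrix(0L, nrow(mask), ncol(mask))
    keep[roi[1L]:roi[3L], roi[2L]:roi[4L]] <- 1L
    mask <- mask * keep
  }
  mask <- remove_small_clusters(mask, min_cluster_size)
  list(probability = pmap, mask = mask, overlay = colorize(mask, image))
}
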