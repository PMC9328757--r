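# Shallow pixel-classification baseline: each pixel is classified from the
# 27 intensities of its 3x3 neighborhood across the red, green and blue
# channels by a small fully-connected network.  This reproduces the
# methodological contrast between purely local color/neighborhood features
# and the U-net's multi-level spatial features.

#' Extract 3x3 neighborhood color features for every pixel
#'
#' For each pixel, the 9 neighborhood intensities of each RGB channel are
#' collected (edge replication at the borders) and normalized to `[0, 1]`,
#' giving a 27-long feature vector whose layout is channel-major: columns
#' 1-9 red, 10-18 green, 19-27 blue, with the center pixel at positions 5,
#' 14 and 23.
#'
#' @param image `H x W x 3` RGB array (0..255 or `[0, 1]`).
#' @return `(H * W) x 27` matrix; rows in column-major pixel order.
#' @export
extract_pixel_features <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("`image` must be an H x W x 3 array")
  H <- d[1L]; W <- d[2L]
  if (H < 3L || W < 3L) stop("image must be at least 3 x 3")
  x <- normalize_intensities(image)
  feat <- matrix(0, H * W, 27L)
  col_idx <- 0L
  for (ch in 1:3) {
    plane <- x[, , ch]
    for (dj in -1:1) {
      cs <- clip(seq_len(W) + dj, 1L, W)
      for (di in -1:1) {
        rs <- clip(seq_len(H) + di, 1L, H)
        col_idx <- col_idx + 1L
        feat[, col_idx] <- as.vector(plane[rs, cs])
      }
    }
  }
  feat
}

#' Pixel-classifier configuration
#'
#' @param hidden Hidden layer sizes of the fully-connected network
#'   (default `c(64, 32)`).
#' @param epochs Training epochs (default 30).
#' @param batch_size Pixels per optimization step (default 256).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param sample_per_class Pixels sampled per class when fitting from
#'   scenes (default 20000).
#' @param threshold Probability threshold for prediction (default 0.5).
#' @param seed Optional integer seed.
#' @return An object of class `pixel_nn_config`.
#' @export
pixel_nn_config <- function(hidden = c(64L, 32L), epochs = 30L,
                            batch_size = 256L, learning_rate = 0.001,
                            sample_per_class = 20000L, threshold = 0.5,
                            seed = NULL) {
  structure(list(hidden = as.integer(hidden), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 sample_per_class = as.integer(sample_per_class),
                 threshold = threshold, seed = seed),
            class = "pixel_nn_config")
}

mlp_forward <- function(weights, x) {
  a <- x
  acts <- list(a)
  nl <- length(weights$W)
  for (l in seq_len(nl)) {
    z <- a %*% weights$W[[l]] + matrix(weights$b[[l]], nrow(a),
                                       length(weights$b[[l]]), byrow = TRUE)
    a <- if (l < nl) z * (z > 0) else 1 / (1 + exp(-z))
    acts[[l + 1L]] <- a
  }
  list(out = a, acts = acts)
}

#' Train the pixel-neighborhood classifier
#'
#' Fits a small fully-connected network (ReLU hidden layers, sigmoid
#' output) on per-pixel 27-feature vectors with Adam and binary
#' cross-entropy.  Callers must supply labels of both classes (balanced or
#' weighted upstream).
#'
#' @param features `n x 27` feature matrix from [extract_pixel_features()].
#' @param labels Length-`n` vector of 0/1 pixel labels.
#' @param config A [pixel_nn_config()].
#' @return An object of class `pixel_nn` holding the fitted weights.
#' @export
train_pixel_nn <- function(features, labels, config = pixel_nn_config()) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  labels <- as.numeric(labels > 0)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; cannot fit a classifier")
  sizes <- c(ncol(features), config$hidden, 1L)
  nl <- length(sizes) - 1L
  weights <- with_seed(config$seed, {
    W <- lapply(seq_len(nl), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                   sqrt(2 / sizes[l])), sizes[l], sizes[l + 1L]))
    b <- lapply(seq_len(nl), function(l) numeric(sizes[l + 1L]))
    list(W = W, b = b)
  })
  m <- lapply(weights$W, function(w) w * 0)
  v <- lapply(weights$W, function(w) w * 0)
  mb <- lapply(weights$b, function(b) b * 0)
  vb <- lapply(weights$b, function(b) b * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7; t_step <- 0L
  n <- nrow(features)
  with_seed(if (is.null(config$seed)) NULL else config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (idx in batches) {
        xb <- features[idx, , drop = FALSE]
        yb <- labels[idx]
        fw <- mlp_forward(weights, xb)
        p <- fw$out
        dz <- (p - yb) / length(yb)
        dW <- vector("list", nl); db <- vector("list", nl)
        for (l in rev(seq_len(nl))) {
          a_prev <- fw$acts[[l]]
          dW[[l]] <- t(a_prev) %*% dz
          db[[l]] <- colSums(dz)
          if (l > 1L) {
            da <- dz %*% t(weights$W[[l]])
            dz <- da * (fw$acts[[l]] > 0)
          }
        }
        t_step <- t_step + 1L
        c1 <- 1 - b1^t_step; c2 <- 1 - b2^t_step
        for (l in seq_len(nl)) {
          m[[l]] <- b1 * m[[l]] + (1 - b1) * dW[[l]]
          v[[l]] <- b2 * v[[l]] + (1 - b2) * dW[[l]]^2
          weights$W[[l]] <- weights$W[[l]] -
            config$learning_rate * (m[[l]] / c1) / (sqrt(v[[l]] / c2) + eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * db[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * db[[l]]^2
          weights$b[[l]] <- weights$b[[l]] -
            config$learning_rate * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
        }
      }
    }
  })
  structure(list(weights = weights, config = config), class = "pixel_nn")
}

#' Predict a plant mask with the pixel classifier
#'
#' @param classifier A `pixel_nn` from [train_pixel_nn()].
#' @param image `H x W x 3` RGB array.
#' @return Integer `H x W` binary mask (probability thresholded at the
#'   configured threshold, default 0.5).
#' @export
predict_pixel_nn <- function(classifier, image) {
  stopifnot(inherits(classifier, "pixel_nn"))
  d <- dim(image)
  feat <- extract_pixel_features(image)
  p <- mlp_forward(classifier$weights, feat)$out
  matrix(as.integer(p >= classifier$config$threshold), d[1L], d[2L])
}

#' Fit the pixel baseline from image/mask pairs
#'
#' Samples an equal number of plant and background pixels
#' (`sample_per_class` each, or fewer if a class is smaller) across all
#' images and trains the classifier on their neighborhood features.
#'
#' @param images List of `H x W x 3` arrays.
#' @param masks List of matching binary masks.
#' @param config A [pixel_nn_config()].
#' @return A fitted `pixel_nn`.
#' @export
fit_pixel_baseline <- function(images, masks, config = pixel_nn_config()) {
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  feats <- list(); labs <- list()
  for (i in seq_along(images)) {
    feats[[i]] <- extract_pixel_features(images[[i]])
    labs[[i]] <- as.numeric(masks[[i]] > 0)
  }
  feat <- do.call(rbind, feats)
  lab <- unlist(labs)
  sel <- with_seed(config$seed, {
    ip <- which(lab == 1); ib <- which(lab == 0)
    np <- min(length(ip), config$sample_per_class)
    nb <- min(length(ib), config$sample_per_class)
    c(if (length(ip) > np) sample(ip, np) else ip,
      if (length(ib) > nb) sample(ib, nb) else ib)
  })
  train_pixel_nn(feat[sel, , drop = FALSE], lab[sel], config)
}
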