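# Independent brute-force oracles used across the suite.  These are written
# for clarity, not speed, and are kept free of the package's own fast paths.

# Naive 'same' zero-padded convolution in double precision.
naive_conv2d <- function(x, w, b) {
  d <- dim(x); H <- d[1]; W <- d[2]; Ci <- d[3]; N <- d[4]
  k <- dim(w)[1]; Co <- dim(w)[4]; p <- (k - 1) / 2
  y <- array(0, c(H, W, Co, N))
  for (n in 1:N) for (co in 1:Co) for (i in 1:H) for (j in 1:W) {
    s <- b[co]
    for (di in 1:k) for (dj in 1:k) for (ci in 1:Ci) {
      si <- i + di - 1 - p; sj <- j + dj - 1 - p
      if (si >= 1 && si <= H && sj >= 1 && sj <= W)
        s <- s + x[si, sj, ci, n] * w[di, dj, ci, co]
    }
    y[i, j, co, n] <- s
  }
  y
}

# Dice from an explicit confusion matrix.
oracle_dice_confusion <- function(P, G) {
  tp <- sum(P == 1 & G == 1)
  fp <- sum(P == 1 & G == 0)
  fn <- sum(P == 0 & G == 1)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# Recursive flood-fill connected-component labelling (queue-based).
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        ni <- cur[1] + o[1]; nj <- cur[2] + o[2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] != 0 && lab[ni, nj] == 0) {
          lab[ni, nj] <- nxt
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# Random blob mask: a few discs on an H x W grid.
random_blob_mask <- function(H, W, n_blobs = 3, rmax = max(3, H %/% 6)) {
  m <- matrix(0L, H, W)
  for (b in seq_len(n_blobs)) {
    r0 <- runif(1, 1, H); c0 <- runif(1, 1, W); rad <- runif(1, 1.5, rmax)
    rows <- matrix(rep(seq_len(H), W), H, W)
    cols <- matrix(rep(seq_len(W), each = H), H, W)
    m[(rows - r0)^2 + (cols - c0)^2 <= rad^2] <- 1L
  }
  m
}

# Small helper building a uniform-color RGB image.
uniform_image <- function(H, W, rgb = c(0, 200, 0)) {
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

tiny_unet_config <- function() {
  unet_config(patch_size = 32L, kernel_size = 3L, depth = 2L,
              encoder_filters = c(2L, 3L), bridge_filters = 4L)
}
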