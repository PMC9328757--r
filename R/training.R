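#' Training configuration
#'
#' Defaults follow the reference shoot-model training protocol: 100 epochs at batch
#' size 128, Adam with initial learning rate 0.001, learning rate reduced by
#' a factor of 0.2 when the validation loss has not improved for 5
#' consecutive epochs, an 85:15 train/validation split, and Gaussian weight
#' initialization with standard deviation 0.05.  A learning-rate floor of
#' 1e-6 keeps the schedule well defined, and the probability threshold used
#' to binarize predictions downstream defaults to 0.6.
#'
#' @param epochs Number of training epochs (default 100).
#' @param batch_size Patches per optimization step (default 128).
#' @param initial_learning_rate Adam learning rate at epoch 1 (default 0.001).
#' @param plateau_factor Multiplicative learning-rate reduction (default 0.2).
#' @param plateau_patience Epochs without validation-loss improvement before
#'   a reduction (default 5).
#' @param split_ratio Training fraction of the train/validation split
#'   (default 0.85).
#' @param init_sd SD of the Gaussian weight initialization (default 0.05).
#' @param seed Optional integer seed making the whole run reproducible.
#' @param probability_threshold Threshold for binarizing probability maps
#'   (default 0.6).
#' @param min_cluster_size Minimum connected-component size kept during mask
#'   cleanup; 0 disables the filter (default 0).
#' @param min_learning_rate Lower bound for the schedule (default 1e-6).
#' @param bn_momentum Momentum of the batch-norm moving statistics
#'   (default 0.9).
#' @param calibrate Platt-scale the head logits against the training
#'   patches after the final epoch, folding the affine correction into the
#'   head weights, so the probability map is calibrated before it meets
#'   the decision threshold (default TRUE).
#' @param verbose Print one line per epoch (default FALSE).
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 100L, batch_size = 128L,
                            initial_learning_rate = 0.001,
                            plateau_factor = 0.2, plateau_patience = 5L,
                            split_ratio = 0.85, init_sd = 0.05, seed = NULL,
                            probability_threshold = 0.6,
                            min_cluster_size = 0L,
                            min_learning_rate = 1e-6, bn_momentum = 0.9,
                            calibrate = TRUE, verbose = FALSE) {
  cfg <- list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              initial_learning_rate = initial_learning_rate,
              plateau_factor = plateau_factor,
              plateau_patience = as.integer(plateau_patience),
              split_ratio = split_ratio, init_sd = init_sd, seed = seed,
              probability_threshold = probability_threshold,
              min_cluster_size = as.integer(min_cluster_size),
              min_learning_rate = min_learning_rate,
              bn_momentum = bn_momentum, calibrate = isTRUE(calibrate),
              verbose = isTRUE(verbose))
  if (cfg$epochs < 1L) stop("`epochs` must be at least 1")
  if (cfg$split_ratio <= 0 || cfg$split_ratio >= 1)
    stop("`split_ratio` must lie strictly between 0 and 1")
  if (cfg$plateau_factor <= 0 || cfg$plateau_factor >= 1)
    stop("`plateau_factor` must lie strictly between 0 and 1")
  if (cfg$probability_threshold <= 0 || cfg$probability_threshold >= 1)
    stop("`probability_threshold` must lie strictly between 0 and 1")
  structure(cfg, class = "training_config")
}

#' Build a balanced patch dataset from image/mask pairs
#'
#' Each image and its mask are zero-padded to a tile multiple and cut into
#' non-overlapping tiles.  A tile is classed as "plant" when it contains at
#' least one plant pixel and "background" otherwise; the majority class is
#' then randomly sub-sampled so both classes contribute in equal proportion.
#' Image intensities are scaled into `[0, 1]`.
#'
#' @param images List of `H x W x 3` arrays (intensities 0..255 or `[0, 1]`).
#' @param masks List of matching `H x W` binary masks.
#' @param seed Optional integer seed for the sub-sampling.
#' @param tile Tile size in pixels (default 256).
#' @return An object of class `patch_dataset`: a list with `x` (list of
#'   `tile x tile x 3` arrays in `[0, 1]`), `y` (list of `tile x tile`
#'   masks), `image_id` and `is_plant` vectors.
#' @export
prepare_balanced_patches <- function(images, masks, seed = NULL, tile = 256L) {
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  xs <- list(); ys <- list(); ids <- integer(0)
  for (i in seq_along(images)) {
    img <- normalize_intensities(images[[i]])
    msk <- masks[[i]]
    if (!identical(dim(img)[1:2], dim(msk)[1:2]))
      stop(sprintf("image %d and its mask differ in size", i))
    pi_ <- suppressWarnings(pad_to_tile_multiple(img, tile))
    pm <- suppressWarnings(pad_to_tile_multiple(msk, tile))
    gi <- extract_patches(pi_$image, pi_$pad_bottom, pi_$pad_right, tile)
    gm <- extract_patches(pm$image, pm$pad_bottom, pm$pad_right, tile)
    for (j in seq_along(gi$patches)) {
      xs[[length(xs) + 1L]] <- gi$patches[[j]]
      ys[[length(ys) + 1L]] <- gm$patches[[j]][, , 1L]
      ids <- c(ids, i)
    }
  }
  is_plant <- vapply(ys, function(y) any(y > 0), logical(1L))
  n_plant <- sum(is_plant)
  n_bg <- sum(!is_plant)
  if (n_plant == 0L) stop("no plant-containing patches: dataset is untrainable")
  keep <- with_seed(seed, {
    ip <- which(is_plant)
    ib <- which(!is_plant)
    if (n_bg == 0L) {
      ip
    } else {
      target <- min(n_plant, n_bg)
      sort(c(if (n_plant > target) sample(ip, target) else ip,
             if (n_bg > target) sample(ib, target) else ib))
    }
  })
  structure(list(x = xs[keep], y = ys[keep], image_id = ids[keep],
                 is_plant = is_plant[keep]),
            class = "patch_dataset")
}

#' @export
length.patch_dataset <- function(x) length(x$x)

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches (%d plant, %d background) from %d images\n",
              length(x$x), sum(x$is_plant), sum(!x$is_plant),
              length(unique(x$image_id))))
  invisible(x)
}

#' Split items into training and validation sets
#'
#' Performs a seeded random, disjoint and exhaustive split; the training set
#' receives `round(split_ratio * N)` items (at least one item stays on each
#' side).
#'
#' @param x Either the number of items, a list of items, or a
#'   `patch_dataset`.
#' @param split_ratio Training fraction (default 0.85).
#' @param seed Optional integer seed.
#' @return For a count: list with integer vectors `train` and `val`.  For a
#'   list or `patch_dataset`: list with elements `train`, `val` (subsets)
#'   plus `train_idx`, `val_idx`.
#' @export
split_train_val <- function(x, split_ratio = 0.85, seed = NULL) {
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("`split_ratio` must lie strictly between 0 and 1")
  n <- if (is_count(x)) as.integer(x)
       else if (inherits(x, "patch_dataset")) length(x$x)
       else length(x)
  if (n < 2L) stop("need at least 2 items to split")
  n_train <- as.integer(round(split_ratio * n))
  n_train <- max(1L, min(n - 1L, n_train))
  ord <- with_seed(seed, sample.int(n))
  ti <- sort(ord[seq_len(n_train)])
  vi <- sort(ord[(n_train + 1L):n])
  if (is_count(x)) return(list(train = ti, val = vi))
  if (inherits(x, "patch_dataset")) {
    sub <- function(idx) structure(list(x = x$x[idx], y = x$y[idx],
                                        image_id = x$image_id[idx],
                                        is_plant = x$is_plant[idx]),
                                   class = "patch_dataset")
    return(list(train = sub(ti), val = sub(vi), train_idx = ti, val_idx = vi))
  }
  list(train = x[ti], val = x[vi], train_idx = ti, val_idx = vi)
}

# Platt scaling of the head logits against labelled patches.  Fits
# sigmoid(a * z + b) to the pixel labels by Newton iterations on the
# binary cross-entropy and folds (a, b) into the 1x1 head convolution, so
# the returned model is still a plain U-net, now with calibrated
# probabilities.  Short training runs learn the decision boundary long
# before the logit amplitude, leaving probabilities compressed around 0.5
# where a fixed decision threshold above 0.5 is meaningless; calibration
# restores the probability scale the threshold presumes.
calibrate_unet_head <- function(model, xs, ys, max_pixels = 300000L) {
  probs <- numeric(0)
  labs <- numeric(0)
  chunks <- split(seq_along(xs), ceiling(seq_along(xs) / 16))
  per_patch <- max(1L, ceiling(max_pixels / length(xs)))
  for (idx in chunks) {
    ba <- batch_arrays(xs, ys, idx)
    p <- unet_forward(model, ba$x, training = FALSE)$prob
    keep <- seq(1L, length(p), by = max(1L, floor(length(p) /
                                                    (per_patch * length(idx)))))
    probs <- c(probs, p[keep])
    labs <- c(labs, ba$y[keep])
  }
  z <- log(pmin(pmax(probs, 1e-7), 1 - 1e-7) /
             (1 - pmin(pmax(probs, 1e-7), 1 - 1e-7)))
  a <- 1; b <- 0
  for (it in 1:25) {
    zz <- pmin(pmax(a * z + b, -30), 30)
    p <- 1 / (1 + exp(-zz))
    w <- pmax(p * (1 - p), 1e-6)
    r <- p - labs
    g <- c(sum(r * z), sum(r))
    H <- matrix(c(sum(w * z * z), sum(w * z), sum(w * z), sum(w)), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e) c(0, 0))
    a <- a - step[1]; b <- b - step[2]
    if (max(abs(step)) < 1e-8) break
  }
  a <- min(max(a, 1e-3), 1e3)
  model$params$head_w <- model$params$head_w * a
  model$params$head_b <- model$params$head_b * a + b
  model$calibration <- c(scale = a, offset = b)
  model
}

# One step of the reduce-on-plateau learning-rate schedule.  `state` holds
# `lr`, `best` (best monitored loss so far) and `wait` (stagnant epochs).
plateau_step <- function(state, val_loss, factor, patience, min_lr) {
  if (val_loss < state$best) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) {
      state$lr <- max(state$lr * factor, min_lr)
      state$wait <- 0L
    }
  }
  state
}

# Assemble (H, W, C, N) / (H, W, 1, N) batch arrays from patch lists.
batch_arrays <- function(xs, ys, idx) {
  xb <- stack_patches(xs[idx])
  d <- dim(xs[[idx[1L]]])
  yb <- array(0, dim = c(d[1L], d[2L], 1L, length(idx)))
  for (q in seq_along(idx)) yb[, , 1L, q] <- ys[[idx[q]]]
  list(x = xb, y = yb)
}

#' Train a U-net on a patch dataset
#'
#' Minimizes pixel-averaged binary cross-entropy with Adam.  Batch-norm
#' layers use batch statistics during training and exponentially averaged
#' moving statistics at validation/inference time.  The learning rate is
#' reduced by `plateau_factor` whenever the validation loss has not improved
#' for `plateau_patience` consecutive epochs (monitoring the training loss
#' when no validation set is supplied).  With a fixed `config$seed` the
#' entire run is reproducible.
#'
#' @param model A `unet_model` from [build_unet()].
#' @param train_x,train_y Lists of training patches (`P x P x 3` arrays in
#'   `[0, 1]`) and masks (`P x P`, values 0/1), or a `patch_dataset` passed
#'   as `train_x`.
#' @param val_x,val_y Optional validation patches/masks in the same format.
#' @param config A [training_config()].
#' @return The trained `unet_model`, with a `history` data frame (per-epoch
#'   `epoch`, `lr`, `train_loss`, `train_dice`, `val_loss`, `val_dice`).
#' @export
train_unet <- function(model, train_x, train_y = NULL, val_x = NULL,
                       val_y = NULL, config = training_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(config, "training_config"))
  if (inherits(train_x, "patch_dataset")) {
    train_y <- train_x$y; train_x <- train_x$x
  }
  if (inherits(val_x, "patch_dataset")) {
    val_y <- val_x$y; val_x <- val_x$x
  }
  n <- length(train_x)
  stopifnot(n >= 1L, length(train_y) == n)
  has_val <- !is.null(val_x) && length(val_x) > 0L
  bn_prefixes <- sub("_rmean$", "", grep("_rmean$", names(model$state),
                                         value = TRUE))
  P <- model$params
  S <- model$state
  adam_m <- lapply(P, function(p) p * 0)
  adam_v <- lapply(P, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-7
  t_step <- 0L
  mom <- config$bn_momentum
  sched <- list(lr = config$initial_learning_rate, best = Inf, wait = 0L)
  history <- vector("list", config$epochs)

  eval_set <- function(xs, ys) {
    m2 <- model; m2$params <- P; m2$state <- S
    tot_loss <- 0; tot_inter <- 0; tot_p <- 0; tot_g <- 0; tot_n <- 0
    chunks <- split(seq_along(xs), ceiling(seq_along(xs) / 16))
    for (idx in chunks) {
      ba <- batch_arrays(xs, ys, idx)
      prob <- unet_forward(m2, ba$x, training = FALSE)$prob
      tot_loss <- tot_loss + binary_cross_entropy(prob, ba$y) * length(idx)
      pm <- prob >= 0.5
      tot_inter <- tot_inter + sum(pm * ba$y)
      tot_p <- tot_p + sum(pm); tot_g <- tot_g + sum(ba$y)
      tot_n <- tot_n + length(idx)
    }
    dn <- tot_p + tot_g
    list(loss = tot_loss / tot_n,
         dice = if (dn == 0) 1 else 2 * tot_inter / dn)
  }

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_inter <- 0; ep_p <- 0; ep_g <- 0; ep_n <- 0
      for (idx in batches) {
        ba <- batch_arrays(train_x, train_y, idx)
        m2 <- model; m2$params <- P; m2$state <- S
        fw <- unet_forward(m2, ba$x, training = TRUE)
        loss <- binary_cross_entropy(fw$prob, ba$y)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d (lr %.2g); aborting",
                       epoch, sched$lr))
        for (bp in bn_prefixes) {
          S[[paste0(bp, "_rmean")]] <- mom * S[[paste0(bp, "_rmean")]] +
            (1 - mom) * fw$cache[[paste0(bp, "_mean")]]
          S[[paste0(bp, "_rvar")]] <- mom * S[[paste0(bp, "_rvar")]] +
            (1 - mom) * fw$cache[[paste0(bp, "_var")]]
        }
        pm <- fw$prob >= 0.5
        ep_loss <- ep_loss + loss * length(idx)
        ep_inter <- ep_inter + sum(pm * ba$y)
        ep_p <- ep_p + sum(pm)
        ep_g <- ep_g + sum(ba$y)
        ep_n <- ep_n + length(idx)
        rm(pm)
        dlogits <- (fw$prob - ba$y) / length(ba$y)
        grads <- unet_backward(m2, fw$cache, dlogits)
        rm(fw)
        t_step <- t_step + 1L
        corr1 <- 1 - b1^t_step
        corr2 <- 1 - b2^t_step
        for (nm in names(P)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g * g
          P[[nm]] <- P[[nm]] - sched$lr * (adam_m[[nm]] / corr1) /
            (sqrt(adam_v[[nm]] / corr2) + adam_eps)
        }
        grads <- NULL
      }
      dn <- ep_p + ep_g
      train_metrics <- list(loss = ep_loss / ep_n,
                            dice = if (dn == 0) 1 else 2 * ep_inter / dn)
      val_metrics <- if (has_val) eval_set(val_x, val_y) else
        list(loss = NA_real_, dice = NA_real_)
      history[[epoch]] <- data.frame(
        epoch = epoch, lr = sched$lr,
        train_loss = train_metrics$loss, train_dice = train_metrics$dice,
        val_loss = val_metrics$loss, val_dice = val_metrics$dice)
      if (config$verbose)
        message(sprintf(
          "epoch %3d  lr %.2g  loss %.4f  dice %.4f  val_loss %s  val_dice %s",
          epoch, sched$lr, train_metrics$loss, train_metrics$dice,
          formatC(val_metrics$loss, format = "f", digits = 4),
          formatC(val_metrics$dice, format = "f", digits = 4)))
      monitored <- if (has_val) val_metrics$loss else train_metrics$loss
      sched <- plateau_step(sched, monitored, config$plateau_factor,
                            config$plateau_patience, config$min_learning_rate)
    }
  })
  model$params <- P
  model$state <- S
  model$history <- do.call(rbind, history)
  model$trained <- TRUE
  if (config$calibrate)
    model <- calibrate_unet_head(model, train_x, train_y)
  model
}

#' End-to-end model fitting from whole images
#'
#' Convenience wrapper: splits the images (not the patches, so that tiles of
#' one image never leak across the split) into training and validation sets
#' at `config$split_ratio`, builds balanced patch datasets for both sides,
#' constructs the network and trains it.
#'
#' @param images List of `H x W x 3` arrays.
#' @param masks List of matching binary masks.
#' @param model_cfg A [unet_config()].
#' @param config A [training_config()].
#' @return A list with the trained `model`, its `history`, and the image
#'   `split` (indices).
#' @export
fit_unet <- function(images, masks, model_cfg = unet_config(),
                     config = training_config()) {
  stopifnot(length(images) == length(masks))
  sp <- split_train_val(length(images), config$split_ratio, seed = config$seed)
  train_ds <- prepare_balanced_patches(images[sp$train], masks[sp$train],
                                       seed = config$seed,
                                       tile = model_cfg$patch_size)
  val_ds <- prepare_balanced_patches(images[sp$val], masks[sp$val],
                                     seed = config$seed,
                                     tile = model_cfg$patch_size)
  model <- build_unet(model_cfg, seed = config$seed, init_sd = config$init_sd)
  model <- train_unet(model, train_ds, val_x = val_ds, config = config)
  list(model = model, history = model$history, split = sp)
}
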