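make_pair <- function(h, w, plant = TRUE, seed = NULL) {
  # one image/mask pair; plant pixels drawn as a centered square
  if (!is.null(seed)) set.seed(seed)
  img <- array(runif(h * w * 3, 0, 255), c(h, w, 3))
  m <- matrix(0L, h, w)
  if (plant) m[(h %/% 2):(h %/% 2 + 4), (w %/% 2):(w %/% 2 + 4)] <- 1L
  list(image = img, mask = m)
}

test_that("patch balancing equalizes plant and background tile counts", {
  set.seed(61)
  # one 256 x 2560 strip: 10 tiles, plant pixels only in the first 4 tiles
  img <- array(runif(256 * 2560 * 3, 0, 255), c(256, 2560, 3))
  m <- matrix(0L, 256, 2560)
  for (q in 0:3) m[100, q * 256 + 10] <- 1L
  ds <- prepare_balanced_patches(list(img), list(m), seed = 1)
  expect_s3_class(ds, "patch_dataset")
  expect_equal(sum(ds$is_plant), 4)
  expect_equal(sum(!ds$is_plant), 4)
  # intensities normalized into [0, 1]
  expect_lte(max(vapply(ds$x, max, 1)), 1)
  # already balanced input is kept in full
  m2 <- matrix(0L, 256, 2560)
  for (q in 0:4) m2[100, q * 256 + 10] <- 1L
  ds2 <- prepare_balanced_patches(list(img), list(m2), seed = 1)
  expect_equal(length(ds2), 10)
  # all-plant mask: every tile classed plant, none dropped
  ds3 <- prepare_balanced_patches(list(img), list(matrix(1L, 256, 2560)),
                                  seed = 1)
  expect_true(all(ds3$is_plant))
  expect_equal(length(ds3), 10)
  # no plant anywhere is untrainable
  expect_error(prepare_balanced_patches(list(img),
                                        list(matrix(0L, 256, 2560))),
               "untrainable")
})

test_that("the train/validation split is 85:15, disjoint and seeded", {
  sp <- split_train_val(100, 0.85, seed = 3)
  expect_length(sp$train, 85)
  expect_length(sp$val, 15)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), 1:100)
  sp20 <- split_train_val(20, 0.85, seed = 3)
  expect_length(sp20$train, 17)
  expect_length(sp20$val, 3)
  # same seed, same membership; different seed, (almost surely) different
  expect_identical(split_train_val(100, 0.85, seed = 7),
                   split_train_val(100, 0.85, seed = 7))
  expect_false(identical(split_train_val(100, 0.85, seed = 7)$train,
                         split_train_val(100, 0.85, seed = 8)$train))
  expect_error(split_train_val(1, 0.85), "at least 2")
  expect_error(split_train_val(10, 1.2), "strictly between")
})

test_that("the plateau schedule reduces the rate by its factor after patience", {
  st <- list(lr = 0.001, best = Inf, wait = 0L)
  st <- shootseg:::plateau_step(st, 0.5, 0.2, 5L, 1e-6)   # improvement
  expect_equal(st$lr, 0.001)
  for (q in 1:4) st <- shootseg:::plateau_step(st, 0.6, 0.2, 5L, 1e-6)
  expect_equal(st$lr, 0.001)           # 4 stagnant epochs: not yet
  st <- shootseg:::plateau_step(st, 0.6, 0.2, 5L, 1e-6)
  expect_equal(st$lr, 0.001 * 0.2)     # 5th stagnant epoch: 0.001 -> 0.0002
  # floor is respected
  st$lr <- 2e-6
  for (q in 1:5) st <- shootseg:::plateau_step(st, 0.6, 0.2, 5L, 1e-6)
  expect_equal(st$lr, 1e-6)
})

test_that("training reduces the loss, records history and is reproducible", {
  set.seed(62)
  xs <- list(); ys <- list()
  for (q in 1:6) {
    img <- array(runif(32 * 32 * 3), c(32, 32, 3))
    m <- matrix(0L, 32, 32)
    m[8:24, 8:24] <- 1L
    img[, , 2][m == 1] <- 1      # bright green square = plant
    xs[[q]] <- img; ys[[q]] <- m
  }
  cfg <- training_config(epochs = 6L, batch_size = 4L, seed = 9)
  run <- function() {
    model <- build_unet(tiny_unet_config(), seed = 9)
    train_unet(model, xs, ys, val_x = xs[5:6], val_y = ys[5:6],
               config = cfg)
  }
  m1 <- run()
  h <- m1$history
  expect_equal(nrow(h), 6)
  expect_equal(h$epoch, 1:6)
  expect_lt(h$train_loss[6], h$train_loss[1])
  # learning-rate sequence: each value is the previous one or factor * it
  for (q in 2:6)
    expect_true(abs(h$lr[q] - h$lr[q - 1]) < 1e-15 ||
                  abs(h$lr[q] - 0.2 * h$lr[q - 1]) < 1e-15)
  expect_true(all(diff(h$lr) <= 1e-15))
  # identical seed reproduces the run exactly
  m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_equal(m1$params, m2$params)
})

test_that("image-level fitting keeps tiles of one image on one side of the split", {
  set.seed(63)
  imgs <- list(); msks <- list()
  for (q in 1:4) {
    p <- make_pair(256, 256)
    imgs[[q]] <- p$image; msks[[q]] <- p$mask
  }
  tcfg <- training_config(epochs = 1L, batch_size = 2L, split_ratio = 0.75,
                          seed = 5)
  mcfg <- unet_config(kernel_size = 3L, encoder_filters = c(2L, 2L, 2L),
                      bridge_filters = 4L)
  fit <- fit_unet(imgs, msks, mcfg, tcfg)
  expect_length(fit$split$train, 3)
  expect_length(fit$split$val, 1)
  expect_s3_class(fit$model$history, "data.frame")
  expect_true(fit$model$trained)
})
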