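test_that("thresholding is inclusive at T and monotone in T", {
  pm <- matrix(c(0.6, 0.599, 0.0, 1.0), 2, 2)
  m <- threshold_probability(pm, 0.6)
  expect_equal(m[1, 1], 1L)   # exactly T -> plant
  expect_equal(m[2, 1], 0L)   # just below T -> background
  expect_equal(threshold_probability(matrix(0, 4, 4)), matrix(0L, 4, 4))
  set.seed(31)
  pm <- matrix(runif(400), 20, 20)
  for (Tn in c(0.2, 0.5, 0.6, 0.9)) {
    m <- threshold_probability(pm, Tn)
    expect_equal(sum(m), sum(pm >= Tn))   # count agreement
  }
  # raising T never adds plant pixels
  ts <- sort(runif(6, 0.05, 0.95))
  masks <- lapply(ts, function(Tn) threshold_probability(pm, Tn))
  for (q in 2:length(masks))
    expect_true(all(masks[[q]] <= masks[[q - 1]]))
  expect_error(threshold_probability(pm, 0), "between 0 and 1")
  expect_error(threshold_probability(pm, 1), "between 0 and 1")
})

test_that("small-cluster removal matches a brute-force component oracle", {
  # documented example: components of sizes {5, 50}, min_size 10
  m <- matrix(0L, 20, 20)
  m[2, 2:6] <- 1L                 # 5 px
  m[10:14, 5:14] <- 1L            # 50 px
  out <- remove_small_clusters(m, 10)
  expect_equal(sum(out), 50)
  expect_equal(out[10:14, 5:14], matrix(1L, 5, 10))

  set.seed(32)
  for (rep in 1:10) {
    mask <- random_blob_mask(40, 40, n_blobs = sample(2:5, 1))
    min_size <- sample(c(0, 3, 10, 40), 1)
    got <- remove_small_clusters(mask, min_size)
    lab <- oracle_label(mask, 8)
    keep_oracle <- mask
    if (min_size > 1 && max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      for (comp in which(sizes < min_size)) keep_oracle[lab == comp] <- 0L
    }
    expect_identical(got, keep_oracle)
    # idempotence
    expect_identical(remove_small_clusters(got, min_size), got)
  }
  # min_size 0 is the identity; min_size beyond total empties the mask
  mask <- random_blob_mask(30, 30)
  expect_identical(remove_small_clusters(mask, 0), mask)
  expect_equal(sum(remove_small_clusters(mask, sum(mask) + 1)), 0)
})

test_that("connectivity 8 keeps diagonal structures that 4 splits", {
  m <- matrix(0L, 6, 6)
  m[cbind(1:5, 1:5)] <- 1L   # diagonal line
  expect_equal(max(shootseg:::cpp_label_components(m, 8L)), 1)
  expect_equal(max(shootseg:::cpp_label_components(m, 4L)), 5)
  expect_equal(sum(remove_small_clusters(m, 3, connectivity = 8)), 5)
  expect_equal(sum(remove_small_clusters(m, 3, connectivity = 4)), 0)
})

test_that("colorize keeps plant pixels and blacks out the background", {
  img <- array(runif(8 * 8 * 3, 1, 255), c(8, 8, 3))
  expect_equal(colorize(matrix(0L, 8, 8), img), array(0, c(8, 8, 3)))
  expect_equal(colorize(matrix(1L, 8, 8), img), img)
  m <- matrix(0L, 8, 8); m[3, 5] <- 1L
  out <- colorize(m, img)
  expect_equal(out[3, 5, ], img[3, 5, ])
  expect_equal(sum(out != 0), 3)
  expect_error(colorize(matrix(0L, 4, 4), img), "match")
})

test_that("whole-image prediction equals direct per-tile evaluation", {
  model <- build_unet(unet_config(kernel_size = 3L,
                                  encoder_filters = c(2L, 3L, 4L),
                                  bridge_filters = 6L), seed = 41)
  set.seed(42)
  img <- array(sample.int(256, 512 * 512 * 3, TRUE) - 1, c(512, 512, 3))
  pm <- predict_probability(model, img)
  expect_equal(dim(pm), c(512, 512))
  expect_true(all(pm >= 0 & pm <= 1))
  # oracle: evaluate each 256-tile independently and stitch by hand
  xn <- img / 255
  for (bi in 0:1) for (bj in 0:1) {
    tile <- xn[bi * 256 + 1:256, bj * 256 + 1:256, , drop = FALSE]
    p <- predict_patches(model, array(tile, c(256, 256, 3, 1)))[, , 1, 1]
    expect_equal(pm[bi * 256 + 1:256, bj * 256 + 1:256], p,
                 tolerance = 1e-12)
  }
})

test_that("prediction pads non-multiple images and crops back", {
  model <- build_unet(unet_config(kernel_size = 3L,
                                  encoder_filters = c(2L, 2L, 2L),
                                  bridge_filters = 4L), seed = 43)
  img <- array(runif(300 * 280 * 3, 0, 255), c(300, 280, 3))
  pm <- predict_probability(model, img)
  expect_equal(dim(pm), c(300, 280))
  seg <- segment_image(model, img, threshold = 0.6, min_cluster_size = 5)
  expect_equal(dim(seg$mask), c(300, 280))
  expect_true(all(seg$mask %in% c(0L, 1L)))
  expect_equal(dim(seg$overlay), dim(img))
})

test_that("an ROI rectangle restricts the segmented region", {
  model <- build_unet(unet_config(kernel_size = 3L,
                                  encoder_filters = c(2L, 2L, 2L),
                                  bridge_filters = 4L), seed = 44)
  img <- array(runif(256 * 256 * 3, 0, 255), c(256, 256, 3))
  seg <- segment_image(model, img, threshold = 0.2,
                       roi = c(50, 60, 100, 120))
  outside <- seg$mask
  outside[50:100, 60:120] <- 0L
  expect_equal(sum(outside), 0)
})
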