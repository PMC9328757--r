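test_that("identical seeds reproduce a scene bit for bit", {
  cfg <- scene_config(seed = 123)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_equal(dim(s1$image), c(256, 256, 3))
  expect_true(all(s1$image >= 0 & s1$image <= 255))
  expect_true(all(s1$mask %in% c(0L, 1L)))
  # different seed differs
  s3 <- generate_scene(scene_config(seed = 124))
  expect_false(identical(s1$image, s3$image))
})

test_that("zero branches yields an empty mask", {
  s <- generate_scene(scene_config(n_branches = c(0L, 0L), seed = 5))
  expect_equal(sum(s$mask), 0)
})

test_that("plant fraction stays within the generator contract", {
  set.seed(71)
  fr_side <- sapply(1:25, function(q)
    mean(generate_scene(scene_config(seed = 1000 + q))$mask))
  fr_top <- sapply(1:15, function(q)
    mean(generate_scene(scene_config(view = "top", seed = 2000 + q))$mask))
  expect_true(all(fr_side >= 0.005 & fr_side <= 0.35))
  expect_true(all(fr_top >= 0.005 & fr_top <= 0.35))
})

test_that("plant pixels are greener than the scene background on average", {
  # the mask must single out colored plant structure, not arbitrary pixels
  s <- generate_scene(scene_config(seed = 33))
  g_plant <- mean(s$image[, , 2][s$mask == 1])
  r_plant <- mean(s$image[, , 1][s$mask == 1])
  g_bg <- mean(s$image[, , 2][s$mask == 0])
  r_bg <- mean(s$image[, , 1][s$mask == 0])
  expect_gt(g_plant - r_plant, g_bg - r_bg)
})

test_that("datasets carry a manifest that reproduces every scene", {
  ds <- generate_dataset(6, scene_config(), seed = 77)
  expect_length(ds$scenes, 6)
  expect_equal(nrow(ds$manifest), 6)
  # per-scene regeneration from recorded seeds
  for (q in c(2, 5)) {
    cfg_q <- ds$config
    cfg_q$seed <- ds$manifest$seed[q]
    s <- generate_scene(cfg_q)
    expect_identical(s$image, ds$scenes[[q]]$image)
    expect_identical(s$mask, ds$scenes[[q]]$mask)
  }
  # same dataset seed -> identical dataset; scenes mutually distinct
  ds2 <- generate_dataset(6, scene_config(), seed = 77)
  expect_identical(ds$manifest$seed, ds2$manifest$seed)
  hashes <- vapply(ds$scenes, function(s) paste(sum(s$image), sum(s$mask)), "")
  expect_false(any(duplicated(hashes)))
})

test_that("written datasets round-trip through disk and manifest", {
  dir <- file.path(tempdir(), "scenes_rt")
  unlink(dir, recursive = TRUE)
  ds <- generate_dataset(3, scene_config(), seed = 11)
  write_dataset(ds, dir)
  expect_length(list.files(file.path(dir, "images")), 3)
  expect_length(list.files(file.path(dir, "masks")), 3)
  img <- read_image(file.path(dir, "images", "scene_001.png"))
  expect_equal(img, ds$scenes[[1]]$image, tolerance = 1e-8)
  m <- read_mask(file.path(dir, "masks", "scene_001.png"))
  expect_identical(m, ds$scenes[[1]]$mask)
  ds_back <- regenerate_dataset(file.path(dir, "manifest.json"))
  expect_identical(ds_back$scenes[[2]]$image, ds$scenes[[2]]$image)
  expect_identical(ds_back$scenes[[3]]$mask, ds$scenes[[3]]$mask)
  unlink(dir, recursive = TRUE)
})

test_that("stressed scenes shift part of the plant toward yellow/brown hues", {
  s_ok <- generate_scene(scene_config(seed = 9))
  s_st <- generate_scene(scene_config(stressed = TRUE, seed = 9))
  hue_of <- function(s) {
    px <- s$mask == 1
    hsv <- grDevices::rgb2hsv(rbind(s$image[, , 1][px], s$image[, , 2][px],
                                    s$image[, , 3][px]), maxColorValue = 255)
    hsv[1, ] * 360
  }
  # stressed scenes contain clearly more sub-65-degree (yellow/brown) pixels
  expect_gt(mean(hue_of(s_st) < 65), mean(hue_of(s_ok) < 65) + 0.1)
})

test_that("scene configuration is validated", {
  expect_error(scene_config(height = 100), "at least 256")
  expect_error(scene_config(n_branches = c(5L, 2L)), "range")
})
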