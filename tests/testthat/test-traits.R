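test_that("the registry defines exactly 35 traits in exactly 4 groups", {
  reg <- trait_registry()
  expect_equal(nrow(reg), 35)
  expect_setequal(unique(reg$group), c("area", "bbox", "hull", "color"))
  expect_equal(as.vector(table(reg$group)[c("area", "bbox", "hull", "color")]),
               c(5, 8, 4, 18))
  expect_false(any(duplicated(reg$name)))
})

test_that("an analytic filled square yields pencil-and-paper trait values", {
  m <- matrix(0L, 100, 100)
  m[5:14, 5:14] <- 1L
  img <- uniform_image(100, 100, c(0, 200, 0))
  tr <- compute_traits(m, img)
  expect_length(tr, 35)
  expect_equal(unname(tr["area.plant_area_px"]), 100)
  expect_equal(unname(tr["area.filled_area_px"]), 100)
  expect_equal(unname(tr["area.area_fraction"]), 100 / 1e4)
  expect_equal(unname(tr["area.component_count"]), 1)
  expect_equal(unname(tr["bbox.min_row"]), 5)
  expect_equal(unname(tr["bbox.min_col"]), 5)
  expect_equal(unname(tr["bbox.height_px"]), 10)
  expect_equal(unname(tr["bbox.width_px"]), 10)
  expect_equal(unname(tr["bbox.area_px"]), 100)
  expect_equal(unname(tr["bbox.extent"]), 1)
  expect_equal(unname(tr["hull.area_px"]), 100)
  expect_equal(unname(tr["hull.solidity"]), 1)
  expect_equal(unname(tr["color.mean_g"]), 200)
  expect_equal(unname(tr["color.mean_r"]), 0)
  expect_equal(unname(tr["color.sd_g"]), 0)
  expect_equal(unname(tr["color.mean_excess_green"]), 400)
  expect_equal(unname(tr["color.mean_norm_green"]), 1)
  expect_equal(unname(tr["color.mean_brightness"]), 200 / 3)
})

test_that("translation changes only the bounding-box origin", {
  set.seed(51)
  m <- matrix(0L, 120, 120)
  m[10:30, 15:40][random_blob_mask(21, 26) > 0] <- 1L
  img <- array(runif(120 * 120 * 3, 0, 255), c(120, 120, 3))
  m2 <- matrix(0L, 120, 120)
  m2[31:51, 36:61] <- m[10:30, 15:40]
  img2 <- img
  img2[31:51, 36:61, ] <- img[10:30, 15:40, ]
  t1 <- compute_traits(m, img)
  t2 <- compute_traits(m2, img2)
  moved <- c("bbox.min_row", "bbox.min_col")
  expect_equal(t2[moved], t1[moved] + 21, ignore_attr = TRUE)
  keep <- setdiff(names(t1), moved)
  expect_equal(t1[keep], t2[keep], tolerance = 1e-10)
})

test_that("disjoint components are counted over the whole shoot", {
  m <- matrix(0L, 60, 60)
  m[5:9, 5:9] <- 1L
  m[40:44, 40:44] <- 1L
  tr <- compute_traits(m, uniform_image(60, 60))
  expect_equal(unname(tr["area.component_count"]), 2)
  expect_equal(unname(tr["area.largest_component_area_px"]), 25)
  expect_equal(unname(tr["area.plant_area_px"]), 50)
})

test_that("hole filling lifts filled area above plant area", {
  m <- matrix(0L, 40, 40)
  m[10:20, 10:20] <- 1L
  m[13:17, 13:17] <- 0L   # interior hole
  tr <- compute_traits(m, uniform_image(40, 40))
  expect_equal(unname(tr["area.plant_area_px"]), 121 - 25)
  expect_equal(unname(tr["area.filled_area_px"]), 121)
})

test_that("area-chain and ratio invariants hold on random blobs", {
  set.seed(52)
  for (rep in 1:15) {
    m <- random_blob_mask(80, 80, n_blobs = sample(1:4, 1))
    if (sum(m) == 0) next
    img <- array(runif(80 * 80 * 3, 0, 255), c(80, 80, 3))
    tr <- compute_traits(m, img)
    expect_lte(tr[["area.plant_area_px"]], tr[["area.filled_area_px"]])
    expect_lte(tr[["area.filled_area_px"]], tr[["hull.area_px"]])
    expect_lte(tr[["hull.area_px"]], tr[["bbox.area_px"]])
    expect_lte(tr[["hull.solidity"]], 1)
    expect_gt(tr[["hull.solidity"]], 0)
    expect_lte(tr[["bbox.extent"]], 1)
    expect_true(all(tr[c("color.mean_r", "color.mean_g", "color.mean_b")] >= 0))
    expect_true(all(tr[c("color.mean_r", "color.mean_g", "color.mean_b")] <= 255))
    expect_true(tr[["color.mean_h"]] >= 0 && tr[["color.mean_h"]] < 360)
    expect_true(tr[["color.mean_s"]] >= 0 && tr[["color.mean_s"]] <= 1)
  }
})

test_that("2x upscaling scales areas ~4x and lengths ~2x", {
  set.seed(53)
  m <- random_blob_mask(50, 50, n_blobs = 2)
  big <- m[rep(seq_len(50), each = 2), rep(seq_len(50), each = 2)]
  t1 <- compute_traits(m, uniform_image(50, 50))
  t2 <- compute_traits(big, uniform_image(100, 100))
  for (nm in c("area.plant_area_px", "hull.area_px", "bbox.area_px"))
    expect_equal(t2[[nm]] / t1[[nm]], 4, tolerance = 0.15)
  for (nm in c("bbox.height_px", "bbox.diagonal_px", "hull.max_diameter_px",
               "hull.perimeter_px"))
    expect_equal(t2[[nm]] / t1[[nm]], 2, tolerance = 0.15)
})

test_that("an empty mask gives zero geometry and missing color traits", {
  tr <- compute_traits(matrix(0L, 30, 30), uniform_image(30, 30))
  geo <- tr[!grepl("^color\\.", names(tr))]
  expect_true(all(geo == 0))
  expect_true(all(is.na(tr[grepl("^color\\.", names(tr))])))
})

test_that("trait tables have stable columns and survive a CSV round trip", {
  empty <- traits_to_table(list())
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(empty), 36)
  set.seed(54)
  recs <- lapply(1:2, function(q)
    compute_traits(random_blob_mask(40, 40),
                   array(runif(40 * 40 * 3, 0, 255), c(40, 40, 3))))
  tab <- traits_to_table(recs, ids = c("a", "b"))
  expect_equal(nrow(tab), 2)
  expect_equal(names(tab), c("id", trait_registry()$name))
  csv <- tempfile(fileext = ".csv")
  traits_to_table(recs, ids = c("a", "b"), out_csv = csv)
  back <- read.csv(csv, check.names = FALSE)
  for (nm in trait_registry()$name)
    expect_equal(back[[nm]], tab[[nm]], tolerance = 1e-6)
  unlink(csv)
})
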