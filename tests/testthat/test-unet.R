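test_that("the default architecture has exactly 2,484,721 trainable parameters", {
  spec <- unet_spec(unet_config())
  expect_identical(sum(spec$params), 2484721)
  # the built model's parameter arrays agree with the closed-form count
  model <- build_unet(unet_config(), seed = 1)
  expect_identical(count_trainable_parameters(model), 2484721L)
  expect_identical(count_trainable_parameters(spec),
                   as.numeric(count_trainable_parameters(model)))
})

test_that("the bridge block emits 128 feature maps of size 32 x 32", {
  spec <- unet_spec(unet_config())
  row <- spec[spec$name == "bridge_conv2_relu", ]
  expect_equal(unlist(row[c("out_h", "out_w", "out_c")], use.names = FALSE),
               c(32, 32, 128))
  row1 <- spec[spec$name == "head_sigmoid", ]
  expect_equal(unlist(row1[c("out_h", "out_w", "out_c")], use.names = FALSE),
               c(256, 256, 1))
})

test_that("a hand-countable toy network matches pencil-and-paper parameter counts", {
  # depth 1, 1x1 kernels, 2 encoder filters, bridge 4:
  #  enc1_conv1 (1*1*3+1)*2 = 8, bn 4; enc1_conv2 (1*2+1)*2 = 6, bn 4
  #  bridge_conv1 (1*2+1)*4 = 12, bn 8; bridge_conv2 (1*4+1)*4 = 20, bn 8
  #  dec1_up (3^2*4+1)*2 = 74; dec1_conv1 (1*(2+2)+1)*2 = 10, bn 4
  #  dec1_conv2 (1*2+1)*2 = 6, bn 4; head (2+1)*1 = 3
  cfg <- unet_config(patch_size = 64L, kernel_size = 1L, depth = 1L,
                     encoder_filters = 2L, bridge_filters = 4L)
  spec <- unet_spec(cfg)
  by_name <- setNames(spec$params, spec$name)
  expect_equal(by_name[["enc1_conv1"]], 8)
  expect_equal(by_name[["enc1_conv2"]], 6)
  expect_equal(by_name[["bridge_conv1"]], 12)
  expect_equal(by_name[["bridge_conv2"]], 20)
  expect_equal(by_name[["dec1_up"]], 74)
  expect_equal(by_name[["dec1_conv1"]], 10)
  expect_equal(by_name[["dec1_conv2"]], 6)
  expect_equal(by_name[["head"]], 3)
  expect_equal(sum(spec$params), 8 + 4 + 6 + 4 + 12 + 8 + 20 + 8 + 74 +
                 10 + 4 + 6 + 4 + 3)
})

test_that("doubling every filter width scales convolution weights about 4x", {
  s1 <- unet_spec(unet_config())
  s2 <- unet_spec(unet_config(encoder_filters = c(32L, 64L, 128L),
                              bridge_filters = 256L))
  sel1 <- s1$type %in% c("conv", "transpose_conv") & s1$name != "head"
  sel2 <- s2$type %in% c("conv", "transpose_conv") & s2$name != "head"
  # first conv has C_in fixed at 3 so it only doubles; the 1-channel head
  # cannot scale; all other layers scale ~4x
  ratio <- s2$params[sel2] / s1$params[sel1]
  expect_true(all(ratio[-1] > 3.6 & ratio[-1] < 4.1))
})

test_that("batch-norm layers account for exactly 2 parameters per conv channel", {
  spec <- unet_spec(unet_config())
  bn_params <- sum(spec$params[spec$type == "batch_norm"])
  conv_channels <- sum(spec$out_c[spec$type == "conv" &
                                    spec$name != "head"])
  expect_equal(bn_params, 2 * conv_channels)
})

test_that("invalid configurations are rejected", {
  expect_error(unet_config(depth = 2L), "one entry per encoder level")
  expect_error(unet_config(patch_size = 100L), "divisible")
  expect_error(unet_config(kernel_size = 4L), "odd")
  expect_error(unet_config(encoder_filters = c(0L, 16L, 32L)), "positive")
})

test_that("forward pass returns a same-size probability map in [0, 1]", {
  model <- build_unet(tiny_unet_config(), seed = 7)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fw <- shootseg:::unet_forward(model, x, training = FALSE)
  expect_equal(dim(fw$prob), c(32, 32, 1, 2))
  expect_true(all(fw$prob >= 0 & fw$prob <= 1))
  # bridge at patch/2^depth with bridge_filters channels
  expect_equal(fw$bridge_dim[1:3], c(8L, 8L, 4L))
  # concat width is upsampled-half plus skip: bridge/2 + filters[2], then
  # filters[2]/2 + filters[1] for this non-pyramid toy config
  spec <- model$spec
  expect_equal(spec$out_c[spec$name == "dec2_concat"], 4 %/% 2 + 3)
  expect_equal(spec$out_c[spec$name == "dec1_concat"], 3 %/% 2 + 2)
  # in the default doubling pyramid every concat is 2 * encoder_filters[d]
  dspec <- unet_spec(unet_config())
  for (d in 1:3)
    expect_equal(dspec$out_c[dspec$name == sprintf("dec%d_concat", d)],
                 2 * c(16, 32, 64)[d])
})

test_that("the convolution kernel agrees with a naive double-precision oracle", {
  set.seed(11)
  x <- array(rnorm(10 * 9 * 2 * 2), c(10, 9, 2, 2))
  for (k in c(1, 3, 7)) {
    w <- array(rnorm(k * k * 2 * 3, 0, 0.5), c(k, k, 2, 3))
    b <- rnorm(3)
    expect_equal(shootseg:::cpp_conv2d_fwd(x, w, b), naive_conv2d(x, w, b),
                 tolerance = 1e-5)
  }
})

test_that("backward kernels match finite differences of double oracles", {
  set.seed(12)
  H <- 6; W <- 5; Ci <- 2; Co <- 3; k <- 3; N <- 2
  x <- array(rnorm(H * W * Ci * N), c(H, W, Ci, N))
  w <- array(rnorm(k * k * Ci * Co), c(k, k, Ci, Co))
  b <- rnorm(Co)
  R <- array(rnorm(H * W * Co * N), c(H, W, Co, N))
  # linear functional sum(conv(.) * R) has exact gradient dy = R
  bw <- shootseg:::cpp_conv2d_bwd(x, w, R)
  eps <- 1e-6
  for (q in 1:8) {
    i <- sample(length(w), 1)
    wp <- w; wp[i] <- w[i] + eps
    wm <- w; wm[i] <- w[i] - eps
    num <- (sum(naive_conv2d(x, wp, b) * R) -
              sum(naive_conv2d(x, wm, b) * R)) / (2 * eps)
    expect_equal(bw$dw[i], num, tolerance = 1e-3)
    j <- sample(length(x), 1)
    xp <- x; xp[j] <- x[j] + eps
    xm <- x; xm[j] <- x[j] - eps
    num <- (sum(naive_conv2d(xp, w, b) * R) -
              sum(naive_conv2d(xm, w, b) * R)) / (2 * eps)
    expect_equal(bw$dx[j], num, tolerance = 1e-3)
  }
  expect_equal(as.numeric(bw$db), apply(R, 3, sum), tolerance = 1e-4)
})

test_that("the transpose convolution doubles spatial size and halves channels", {
  ns <- asNamespace("shootseg")
  set.seed(13)
  xt <- array(rnorm(4 * 3 * 4 * 2), c(4, 3, 4, 2))
  wt <- array(rnorm(3 * 3 * 2 * 4, 0, 0.3), c(3, 3, 2, 4))
  bt <- rnorm(2)
  y <- ns$ft_to_array(ns$ft_tconv2d_fwd(ns$ft_from_array(xt), wt, bt))
  expect_equal(dim(y), c(8, 6, 2, 2))
  # scatter oracle: out[2i+di-1, 2j+dj-1] += x[i,j,ci] * w[di,dj,co,ci]
  yo <- array(0, c(8, 6, 2, 2))
  for (n in 1:2) for (co in 1:2) {
    for (i in 1:4) for (j in 1:3) for (di in 1:3) for (dj in 1:3) {
      r <- 2 * (i - 1) + di - 1 + 1; cc <- 2 * (j - 1) + dj - 1 + 1
      if (r <= 8 && cc <= 6)
        for (ci in 1:4)
          yo[r, cc, co, n] <- yo[r, cc, co, n] +
            xt[i, j, ci, n] * wt[di, dj, co, ci]
    }
    yo[, , co, n] <- yo[, , co, n] + bt[co]
  }
  expect_equal(y, yo, tolerance = 1e-5)
})

test_that("training-mode gradients of the full network match finite differences", {
  # checked in double precision at the parameters with the largest
  # analytic gradients, where float forward noise is negligible
  model <- build_unet(tiny_unet_config(), seed = 2)
  ns <- asNamespace("shootseg")
  set.seed(3)
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  g <- array(rbinom(32 * 32 * 2, 1, 0.3), c(32, 32, 1, 2))
  fw <- ns$unet_forward(model, x, training = TRUE)
  gr <- ns$unet_backward(model, fw$cache, (fw$prob - g) / length(g))
  loss_fn <- function(m)
    binary_cross_entropy(ns$unet_forward(m, x, training = TRUE)$prob, g)
  checked <- 0
  for (nm in names(model$params)) {
    i <- which.max(abs(gr[[nm]]))
    ana <- gr[[nm]][i]
    if (abs(ana) < 1e-4) next   # below float finite-difference noise floor
    eps <- 1e-4
    mp <- model; mp$params[[nm]][i] <- model$params[[nm]][i] + eps
    mm <- model; mm$params[[nm]][i] <- model$params[[nm]][i] - eps
    num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
    expect_equal(ana, num, tolerance = 0.05)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("models round-trip through save/load and export their spec as JSON", {
  model <- build_unet(tiny_unet_config(), seed = 5)
  f <- tempfile(fileext = ".rds")
  save_unet(model, f)
  m2 <- load_unet(f)
  expect_equal(m2$params, model$params)
  js <- tempfile(fileext = ".json")
  export_network_spec(model, js)
  spec <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(spec), nrow(model$spec))
  expect_equal(sum(spec$params), count_trainable_parameters(model))
  unlink(c(f, js))
})
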