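#' U-net architecture configuration
#'
#' Describes the batch-normalized encoder-decoder U-net.  The defaults
#' reproduce the shoot segmentation network: 256x256x3 input patches, three
#' encoder blocks of 7x7 convolutions with 16/32/64 filters, a 128-filter
#' bridge block, and a decoder whose 3x3 stride-2 transpose convolutions
#' double the spatial size while halving the channel depth before each skip
#' concatenation.  Every convolution is followed by batch normalization and
#' ReLU; the head is a single-channel 1x1 convolution with sigmoid
#' activation, and there is no dropout.
#'
#' @param patch_size Input patch side length in pixels; must be divisible by
#'   `2^depth` (default 256).
#' @param kernel_size Side of the square convolution kernels (default 7).
#' @param transpose_kernel_size Side of the transpose-convolution kernels
#'   (default 3).
#' @param transpose_stride Upsampling stride of the transpose convolutions
#'   (default 2; the only supported value).
#' @param depth Number of encoder blocks / pooling stages (default 3); the
#'   bridge block is counted separately.
#' @param encoder_filters Channel counts of the encoder blocks, one per
#'   level (default `c(16, 32, 64)`).
#' @param bridge_filters Channel count of the bridge block (default 128).
#' @param input_channels Input channels (default 3, RGB).
#' @param output_channels Output channels (default 1, plant probability).
#' @return An object of class `unet_config`.
#' @examples
#' cfg <- unet_config()
#' count_trainable_parameters(unet_spec(cfg))
#' @export
unet_config <- function(patch_size = 256L, kernel_size = 7L,
                        transpose_kernel_size = 3L, transpose_stride = 2L,
                        depth = 3L, encoder_filters = c(16L, 32L, 64L),
                        bridge_filters = 128L, input_channels = 3L,
                        output_channels = 1L) {
  cfg <- list(patch_size = as.integer(patch_size),
              kernel_size = as.integer(kernel_size),
              transpose_kernel_size = as.integer(transpose_kernel_size),
              transpose_stride = as.integer(transpose_stride),
              depth = as.integer(depth),
              encoder_filters = as.integer(encoder_filters),
              bridge_filters = as.integer(bridge_filters),
              input_channels = as.integer(input_channels),
              output_channels = as.integer(output_channels))
  if (length(cfg$encoder_filters) != cfg$depth)
    stop("`encoder_filters` must have one entry per encoder level (depth)")
  if (any(unlist(cfg) <= 0)) stop("all configuration counts must be positive")
  if (cfg$patch_size %% 2L^cfg$depth != 0L)
    stop("`patch_size` must be divisible by 2^depth")
  if (cfg$kernel_size %% 2L == 0L)
    stop("`kernel_size` must be odd ('same' zero padding)")
  if (cfg$transpose_stride != 2L)
    stop("only transpose stride 2 (spatial doubling) is supported")
  structure(cfg, class = "unet_config")
}

#' Layer-by-layer network specification
#'
#' Walks the architecture defined by a [unet_config()] and returns one row
#' per layer with its operation kind, output spatial size, channel depth and
#' trainable-parameter count: `(k^2 * C_in + 1) * C_out` for (transpose)
#' convolutions and `2 * C` scale/offset parameters per batch-norm layer
#' (moving statistics are non-trainable and excluded).
#'
#' @param config A [unet_config()].
#' @return A data frame of class `unet_spec` with columns `name`, `type`,
#'   `out_h`, `out_w`, `out_c`, `params`.
#' @export
unet_spec <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  k <- config$kernel_size
  tk <- config$transpose_kernel_size
  rows <- list()
  add <- function(name, type, h, w, c, params) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, type = type, out_h = h, out_w = w, out_c = c,
      params = params, stringsAsFactors = FALSE)
  }
  add_conv_block <- function(prefix, cin, cout, h, w, ksize) {
    add(prefix, "conv", h, w, cout, (ksize^2 * cin + 1) * cout)
    add(paste0(prefix, "_bn"), "batch_norm", h, w, cout, 2 * cout)
    add(paste0(prefix, "_relu"), "relu", h, w, cout, 0)
  }
  h <- config$patch_size; w <- config$patch_size
  cin <- config$input_channels
  add("input", "input", h, w, cin, 0)
  for (d in seq_len(config$depth)) {
    f <- config$encoder_filters[d]
    add_conv_block(sprintf("enc%d_conv1", d), cin, f, h, w, k)
    add_conv_block(sprintf("enc%d_conv2", d), f, f, h, w, k)
    h <- h %/% 2L; w <- w %/% 2L
    add(sprintf("enc%d_pool", d), "max_pool", h, w, f, 0)
    cin <- f
  }
  add_conv_block("bridge_conv1", cin, config$bridge_filters, h, w, k)
  add_conv_block("bridge_conv2", config$bridge_filters, config$bridge_filters,
                 h, w, k)
  cprev <- config$bridge_filters
  for (d in rev(seq_len(config$depth))) {
    f <- config$encoder_filters[d]
    cup <- max(cprev %/% 2L, 1L)   # transpose convolution halves channel depth
    h <- h * 2L; w <- w * 2L
    add(sprintf("dec%d_up", d), "transpose_conv", h, w, cup,
        (tk^2 * cprev + 1) * cup)
    add(sprintf("dec%d_concat", d), "concat", h, w, cup + f, 0)
    add_conv_block(sprintf("dec%d_conv1", d), cup + f, f, h, w, k)
    add_conv_block(sprintf("dec%d_conv2", d), f, f, h, w, k)
    cprev <- f
  }
  add("head", "conv", h, w, config$output_channels,
      (1 * cprev + 1) * config$output_channels)
  add("head_sigmoid", "activation", h, w, config$output_channels, 0)
  out <- do.call(rbind, rows)
  class(out) <- c("unet_spec", "data.frame")
  out
}

#' Count trainable parameters
#'
#' For a network specification this sums the per-layer counts; for a built
#' model it sums the lengths of the actual parameter arrays (convolution and
#' transpose-convolution weights and biases plus batch-norm scale/offset
#' pairs; batch-norm moving statistics are excluded).  The two routes must
#' agree exactly.
#'
#' @param x A `unet_spec` or `unet_model`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(x) {
  if (inherits(x, "unet_spec")) return(sum(x$params))
  if (inherits(x, "unet_model")) return(sum(vapply(x$params, length, 1L)))
  stop("`x` must be a unet_spec or unet_model")
}

#' Build a trainable U-net
#'
#' Allocates all parameter arrays for the architecture described by
#' `config`.  Convolution and transpose-convolution kernels are initialized
#' from a zero-mean Gaussian with standard deviation `init_sd`; biases start
#' at zero and batch-norm layers at scale 1 / offset 0 with zero-mean,
#' unit-variance moving statistics.
#'
#' @param config A [unet_config()].
#' @param seed Optional integer seed for reproducible initialization (the
#'   caller's RNG state is preserved).
#' @param init_sd Standard deviation of the Gaussian weight initialization
#'   (default 0.05).
#' @return An object of class `unet_model`: a list with `config`, `spec`
#'   (the layer table), `params` (named trainable arrays) and `state`
#'   (batch-norm moving statistics).
#' @export
build_unet <- function(config = unet_config(), seed = NULL, init_sd = 0.05) {
  stopifnot(inherits(config, "unet_config"))
  spec <- unet_spec(config)
  k <- config$kernel_size
  tk <- config$transpose_kernel_size
  params <- list()
  state <- list()
  with_seed(seed, {
    mk_conv <- function(prefix, cin, cout, ksize) {
      params[[paste0(prefix, "_w")]] <<-
        array(rnorm(ksize^2 * cin * cout, 0, init_sd), dim = c(ksize, ksize, cin, cout))
      params[[paste0(prefix, "_b")]] <<- numeric(cout)
      params[[paste0(prefix, "_gamma")]] <<- rep(1, cout)
      params[[paste0(prefix, "_beta")]] <<- numeric(cout)
      state[[paste0(prefix, "_rmean")]] <<- numeric(cout)
      state[[paste0(prefix, "_rvar")]] <<- rep(1, cout)
    }
    cin <- config$input_channels
    for (d in seq_len(config$depth)) {
      f <- config$encoder_filters[d]
      mk_conv(sprintf("enc%d_conv1", d), cin, f, k)
      mk_conv(sprintf("enc%d_conv2", d), f, f, k)
      cin <- f
    }
    mk_conv("bridge_conv1", cin, config$bridge_filters, k)
    mk_conv("bridge_conv2", config$bridge_filters, config$bridge_filters, k)
    cprev <- config$bridge_filters
    for (d in rev(seq_len(config$depth))) {
      f <- config$encoder_filters[d]
      cup <- max(cprev %/% 2L, 1L)
      params[[sprintf("dec%d_up_w", d)]] <-
        array(rnorm(tk^2 * cup * cprev, 0, init_sd), dim = c(tk, tk, cup, cprev))
      params[[sprintf("dec%d_up_b", d)]] <- numeric(cup)
      mk_conv(sprintf("dec%d_conv1", d), cup + f, f, k)
      mk_conv(sprintf("dec%d_conv2", d), f, f, k)
      cprev <- f
    }
    params$head_w <- array(rnorm(cprev * config$output_channels, 0, init_sd),
                           dim = c(1L, 1L, cprev, config$output_channels))
    params$head_b <- numeric(config$output_channels)
  })
  structure(list(config = config, spec = spec, params = params, state = state,
                 bn_eps = 1e-3, trained = FALSE, history = NULL),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> depth %d, filters [%s], bridge %d, %dx%d patches, %s parameters%s\n",
              x$config$depth, paste(x$config$encoder_filters, collapse = ", "),
              x$config$bridge_filters, x$config$patch_size, x$config$patch_size,
              format(count_trainable_parameters(x), big.mark = ","),
              if (isTRUE(x$trained)) " (trained)" else ""))
  invisible(x)
}

# Full forward pass over an (H, W, C, N) patch batch.  Activations flow
# between the layer kernels as single-precision tensors held in external
# pointers; only the head probabilities come back as a double array.  In
# training mode batch statistics are used for normalization and all
# intermediates needed by unet_backward() are cached; in inference mode the
# moving statistics are used and no cache is kept.
unet_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  P <- model$params
  S <- model$state
  eps <- model$bn_eps
  d4 <- dim(x)
  if (length(d4) != 4L || d4[3L] != cfg$input_channels)
    stop("input must be an (H, W, C, N) array matching the configured channels")
  if (d4[1L] %% 2L^cfg$depth != 0L || d4[2L] %% 2L^cfg$depth != 0L)
    stop("input spatial size must be divisible by 2^depth")
  cache <- list()
  conv_block <- function(x, prefix) {
    z <- ft_conv2d_fwd(x, P[[paste0(prefix, "_w")]], P[[paste0(prefix, "_b")]])
    if (training) {
      bn <- ft_bn_relu_fwd(z, P[[paste0(prefix, "_gamma")]],
                           P[[paste0(prefix, "_beta")]], eps, TRUE)
      y <- bn$y
      cache[[paste0(prefix, "_mean")]] <<- bn$mean
      cache[[paste0(prefix, "_var")]] <<- bn$var
      cache[[paste0(prefix, "_x")]] <<- x
      cache[[paste0(prefix, "_z")]] <<- z
      cache[[paste0(prefix, "_y")]] <<- y
    } else {
      y <- ft_bn_infer(z, P[[paste0(prefix, "_gamma")]],
                       P[[paste0(prefix, "_beta")]],
                       S[[paste0(prefix, "_rmean")]],
                       S[[paste0(prefix, "_rvar")]], eps, TRUE)
    }
    y
  }
  cur <- ft_from_array(x)
  skips <- vector("list", cfg$depth)
  for (d in seq_len(cfg$depth)) {
    cur <- conv_block(cur, sprintf("enc%d_conv1", d))
    cur <- conv_block(cur, sprintf("enc%d_conv2", d))
    skips[[d]] <- cur
    if (training) cache[[sprintf("pool%d_in_hw", d)]] <- ft_dims(cur)[1:2]
    mp <- ft_maxpool2_fwd(cur)
    if (training) cache[[sprintf("pool%d_idx", d)]] <- mp$idx
    cur <- mp$y
  }
  cur <- conv_block(cur, "bridge_conv1")
  cur <- conv_block(cur, "bridge_conv2")
  bridge_dim <- ft_dims(cur)
  for (d in rev(seq_len(cfg$depth))) {
    prefix <- sprintf("dec%d", d)
    if (training) cache[[paste0(prefix, "_up_x")]] <- cur
    up <- ft_tconv2d_fwd(cur, P[[paste0(prefix, "_up_w")]],
                         P[[paste0(prefix, "_up_b")]])
    if (training) cache[[paste0(prefix, "_concat_cup")]] <- ft_dims(up)[3L]
    cur <- ft_concat(up, skips[[d]])
    skips[d] <- list(NULL)
    cur <- conv_block(cur, paste0(prefix, "_conv1"))
    cur <- conv_block(cur, paste0(prefix, "_conv2"))
  }
  if (training) cache$head_x <- cur
  z <- ft_conv2d_fwd(cur, P$head_w, P$head_b)
  prob <- ft_sigmoid(z)
  list(prob = prob, cache = if (training) cache else NULL,
       bridge_dim = bridge_dim)
}

# Backpropagate the gradient of the loss with respect to the head logits
# through the whole network; returns a named list of parameter gradients
# matching model$params.
unet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  P <- model$params
  eps <- model$bn_eps
  grads <- list()
  conv_block_bwd <- function(dy, prefix) {
    bnb <- ft_bn_relu_bwd(cache[[paste0(prefix, "_z")]],
                          cache[[paste0(prefix, "_y")]],
                          P[[paste0(prefix, "_gamma")]],
                          cache[[paste0(prefix, "_mean")]],
                          cache[[paste0(prefix, "_var")]], dy, eps, TRUE)
    grads[[paste0(prefix, "_gamma")]] <<- bnb$dgamma
    grads[[paste0(prefix, "_beta")]] <<- bnb$dbeta
    cb <- ft_conv2d_bwd(cache[[paste0(prefix, "_x")]],
                        P[[paste0(prefix, "_w")]], bnb$dx)
    grads[[paste0(prefix, "_w")]] <<- cb$dw
    grads[[paste0(prefix, "_b")]] <<- cb$db
    cb$dx
  }
  hb <- ft_conv2d_bwd(cache$head_x, P$head_w, ft_from_array(dlogits))
  grads$head_w <- hb$dw
  grads$head_b <- hb$db
  dcur <- hb$dx
  dskips <- vector("list", cfg$depth)
  for (d in seq_len(cfg$depth)) {
    prefix <- sprintf("dec%d", d)
    dcur <- conv_block_bwd(dcur, paste0(prefix, "_conv2"))
    dcur <- conv_block_bwd(dcur, paste0(prefix, "_conv1"))
    sp <- ft_split_channels(dcur, cache[[paste0(prefix, "_concat_cup")]])
    dskips[[d]] <- sp$rest
    tb <- ft_tconv2d_bwd(cache[[paste0(prefix, "_up_x")]],
                         P[[paste0(prefix, "_up_w")]], sp$first)
    grads[[paste0(prefix, "_up_w")]] <- tb$dw
    grads[[paste0(prefix, "_up_b")]] <- tb$db
    dcur <- tb$dx
  }
  dcur <- conv_block_bwd(dcur, "bridge_conv2")
  dcur <- conv_block_bwd(dcur, "bridge_conv1")
  for (d in rev(seq_len(cfg$depth))) {
    hw <- cache[[sprintf("pool%d_in_hw", d)]]
    dpool <- ft_maxpool2_bwd(dcur, cache[[sprintf("pool%d_idx", d)]],
                             hw[1L], hw[2L])
    dy <- ft_add(dpool, dskips[[d]])
    dy <- conv_block_bwd(dy, sprintf("enc%d_conv2", d))
    dcur <- conv_block_bwd(dy, sprintf("enc%d_conv1", d))
  }
  grads
}

#' Predict plant probabilities for a batch of patches
#'
#' Runs the network in inference mode (batch-norm moving statistics) on an
#' `(H, W, C, N)` array of normalized patches.
#'
#' @param model A `unet_model`.
#' @param x `(H, W, C, N)` array with intensities in `[0, 1]`.
#' @return `(H, W, output_channels, N)` array of probabilities in `[0, 1]`.
#' @export
predict_patches <- function(model, x) {
  stopifnot(inherits(model, "unet_model"))
  unet_forward(model, x, training = FALSE)$prob
}

#' Save / load a U-net model
#'
#' Models are serialized with R's native RDS format (configuration,
#' trainable parameters, batch-norm moving statistics and training history).
#' The layer table can be exported as JSON with [export_network_spec()].
#'
#' @param model A `unet_model`.
#' @param path Destination / source file path.
#' @return `save_unet` returns `path` invisibly; `load_unet` returns the
#'   model.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "unet_model")) stop("file does not contain a unet_model")
  model
}

#' Export the layer specification as JSON
#'
#' @param x A `unet_model` or `unet_spec`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
export_network_spec <- function(x, path) {
  spec <- if (inherits(x, "unet_model")) x$spec else x
  stopifnot(inherits(spec, "unet_spec"))
  jsonlite::write_json(as.data.frame(spec), path, dataframe = "rows",
                       pretty = TRUE)
  invisible(path)
}
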