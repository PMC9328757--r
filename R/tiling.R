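#' Zero-pad an image to a tile-size multiple
#'
#' Pads an image (or mask / probability map) with zeros on the bottom and
#' right edges so that both spatial dimensions become the smallest multiples
#' of `tile` that are at least as large as the originals.  Top-left anchoring
#' keeps the original pixel coordinates unchanged, which matters for
#' downstream trait geometry.
#'
#' @param image A numeric `H x W` matrix or `H x W x C` array.
#' @param tile Tile side length in pixels (default 256).
#' @return A list with elements `image` (the padded array), `pad_bottom` and
#'   `pad_right` (pixels added on each edge).
#' @examples
#' p <- pad_to_tile_multiple(matrix(1, 300, 500))
#' dim(p$image)       # 512 x 512
#' c(p$pad_bottom, p$pad_right)
#' @export
pad_to_tile_multiple <- function(image, tile = 256L) {
  if (!is_count(tile) || tile <= 0) stop("`tile` must be a positive integer")
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop("`image` must be a matrix or array")
  h <- d[1L]; w <- d[2L]
  if (h < 1L || w < 1L) stop("`image` must be non-empty")
  if (h < tile || w < tile)
    warning(sprintf("image (%d x %d) is smaller than the %d x %d tile; padding up",
                    h, w, tile, tile))
  hp <- as.integer(tile * ceiling(h / tile))
  wp <- as.integer(tile * ceiling(w / tile))
  nc <- if (length(d) == 3L) d[3L] else 1L
  was_matrix <- length(d) == 2L
  out <- array(0, dim = c(hp, wp, nc))
  out[seq_len(h), seq_len(w), ] <- image
  if (was_matrix) out <- out[, , 1L]
  list(image = out, pad_bottom = hp - h, pad_right = wp - w)
}

#' Cut a padded image into a grid of non-overlapping tiles
#'
#' The image dimensions must be exact multiples of `tile` (use
#' [pad_to_tile_multiple()] first).  Tiles are stored in row-major grid
#' order; together with the recorded geometry this makes [reassemble()] an
#' exact inverse.
#'
#' @param image Padded matrix or array whose spatial dimensions are
#'   divisible by `tile`.
#' @param pad_bottom,pad_right Padding previously added, so the original
#'   size can be recorded (default 0).
#' @param tile Tile side length in pixels (default 256).
#' @return An object of class `patch_grid`: a list with `patches` (list of
#'   `tile x tile x C` arrays), `grid_rows`, `grid_cols`, `tile`,
#'   `channels`, `original_height`, `original_width`, `pad_bottom`,
#'   `pad_right`.
#' @export
extract_patches <- function(image, pad_bottom = 0L, pad_right = 0L, tile = 256L) {
  if (!is_count(tile) || tile <= 0) stop("`tile` must be a positive integer")
  d <- dim(image)
  if (is.null(d) || length(d) < 2L) stop("`image` must be a matrix or array")
  h <- d[1L]; w <- d[2L]
  if (h %% tile != 0L || w %% tile != 0L)
    stop(sprintf("dimensions (%d x %d) are not multiples of the tile size %d",
                 h, w, tile))
  if (pad_bottom < 0L || pad_bottom >= tile || pad_right < 0L || pad_right >= tile)
    stop("padding must lie in [0, tile)")
  nc <- if (length(d) == 3L) d[3L] else 1L
  arr <- if (length(d) == 2L) array(image, dim = c(h, w, 1L)) else image
  gr <- h %/% tile
  gc <- w %/% tile
  patches <- vector("list", gr * gc)
  idx <- 1L
  for (i in seq_len(gr)) {          # row-major grid order
    rows <- ((i - 1L) * tile + 1L):(i * tile)
    for (j in seq_len(gc)) {
      cols <- ((j - 1L) * tile + 1L):(j * tile)
      patches[[idx]] <- arr[rows, cols, , drop = FALSE]
      idx <- idx + 1L
    }
  }
  structure(list(
    patches = patches, grid_rows = gr, grid_cols = gc, tile = as.integer(tile),
    channels = nc,
    original_height = as.integer(h - pad_bottom),
    original_width = as.integer(w - pad_right),
    pad_bottom = as.integer(pad_bottom), pad_right = as.integer(pad_right)
  ), class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf(
    "<patch_grid> %d x %d tiles of %d px (%d channel%s), original %d x %d, pad (%d, %d)\n",
    x$grid_rows, x$grid_cols, x$tile, x$channels, if (x$channels == 1L) "" else "s",
    x$original_height, x$original_width, x$pad_bottom, x$pad_right))
  invisible(x)
}

#' Reassemble a patch grid into the original-size image
#'
#' Stitches the tiles back in row-major order and crops away the padding so
#' the output has exactly the recorded original dimensions.
#'
#' @param grid A `patch_grid` from [extract_patches()].
#' @return An `H x W x C` array (or `H x W` matrix when the grid holds a
#'   single channel) with the recorded original dimensions.
#' @export
reassemble <- function(grid) {
  if (!inherits(grid, "patch_grid")) stop("`grid` must be a patch_grid")
  tile <- grid$tile
  if (length(grid$patches) != grid$grid_rows * grid$grid_cols)
    stop("patch count does not match the recorded grid geometry")
  nc <- grid$channels
  out <- array(0, dim = c(grid$grid_rows * tile, grid$grid_cols * tile, nc))
  idx <- 1L
  for (i in seq_len(grid$grid_rows)) {
    rows <- ((i - 1L) * tile + 1L):(i * tile)
    for (j in seq_len(grid$grid_cols)) {
      cols <- ((j - 1L) * tile + 1L):(j * tile)
      p <- grid$patches[[idx]]
      if (is.null(dim(p)) || dim(p)[1L] != tile || dim(p)[2L] != tile)
        stop("patch dimensions do not match the tile size")
      out[rows, cols, ] <- p
      idx <- idx + 1L
    }
  }
  out <- out[seq_len(grid$original_height), seq_len(grid$original_width), ,
             drop = FALSE]
  if (nc == 1L) out <- out[, , 1L]
  out
}
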