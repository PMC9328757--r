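# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  `seed = NULL` runs under the ambient RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Stack a list of (H, W, C) arrays (or H x W matrices, promoted to one
# channel) into a single (H, W, C, N) array.
stack_patches <- function(lst) {
  stopifnot(length(lst) >= 1L)
  first <- lst[[1L]]
  d <- dim(first)
  if (length(d) == 2L) d <- c(d, 1L)
  out <- array(0, dim = c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

# Clip values into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == as.integer(x)
}

# Scale an image to [0, 1] doubles regardless of whether it arrives as
# 0..255 intensities or already normalized.
normalize_intensities <- function(image) {
  if (max(image) > 1.5) image / 255 else image
}
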