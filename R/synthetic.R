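#' Synthetic greenhouse scene configuration
#'
#' Parameters of the seeded scene generator that emulates greenhouse
#' phenotyping images: a colored background wall with an illumination
#' gradient, pot/carrier-like distractor shapes, a soft shadow under the
#' plant, additive sensor noise, and a branching green plant rendered with
#' hard (alias-free) edges so the ground-truth mask is pixel-exact.
#'
#' @param height,width Scene size in pixels (at least 256; default 256).
#' @param view `"side"` (upward stem with branches and leaf blobs) or
#'   `"top"` (rosette of radial shoots).
#' @param n_branches Integer range `c(min, max)` of branches (default
#'   `c(5, 10)`); a drawn value of 0 yields an empty scene with no plant.
#' @param branch_length Pixel range of branch lengths (default
#'   `c(40, 110)`).
#' @param leaf_blob_radius Pixel range of the elliptical leaf blobs
#'   (default `c(6, 14)`).
#' @param plant_hue_range Hue range in degrees for healthy plant material
#'   (default `c(75, 150)`, greens).
#' @param stressed Logical; when `TRUE` a fraction of the plant is drawn in
#'   stressed (yellow/brown) hues (default `FALSE`).
#' @param stressed_hue_range Hue range in degrees for stressed material
#'   (default `c(25, 60)`).
#' @param stressed_fraction Fraction of primitives drawn in stressed hues
#'   when `stressed = TRUE` (default 0.5).
#' @param background_base_color RGB triple of the background wall (default
#'   `c(70, 72, 78)`).
#' @param background_gradient_strength Peak intensity of the illumination
#'   gradient (default 45).
#' @param distractor_count Integer range of pot/carrier distractors
#'   (default `c(1, 4)`).
#' @param shadow_strength Fractional darkening under the plant in `[0, 1]`
#'   (default 0.35).
#' @param noise_sd SD of the additive Gaussian intensity noise (default 4).
#' @param seed Optional integer seed; the same seed reproduces the scene
#'   bit for bit.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 256L, width = 256L,
                         view = c("side", "top"),
                         n_branches = c(5L, 10L), branch_length = c(40, 110),
                         leaf_blob_radius = c(6, 14),
                         plant_hue_range = c(75, 150),
                         stressed = FALSE, stressed_hue_range = c(25, 60),
                         stressed_fraction = 0.5,
                         background_base_color = c(70, 72, 78),
                         background_gradient_strength = 45,
                         distractor_count = c(1L, 4L),
                         shadow_strength = 0.35, noise_sd = 4,
                         seed = NULL) {
  view <- match.arg(view)
  cfg <- list(height = as.integer(height), width = as.integer(width),
              view = view, n_branches = as.integer(n_branches),
              branch_length = branch_length,
              leaf_blob_radius = leaf_blob_radius,
              plant_hue_range = plant_hue_range, stressed = isTRUE(stressed),
              stressed_hue_range = stressed_hue_range,
              stressed_fraction = stressed_fraction,
              background_base_color = background_base_color,
              background_gradient_strength = background_gradient_strength,
              distractor_count = as.integer(distractor_count),
              shadow_strength = shadow_strength, noise_sd = noise_sd,
              seed = seed)
  if (cfg$height < 256L || cfg$width < 256L)
    stop("scene dimensions must be at least 256 x 256")
  for (f in c("n_branches", "branch_length", "leaf_blob_radius",
              "plant_hue_range", "stressed_hue_range", "distractor_count"))
    if (length(cfg[[f]]) != 2L || cfg[[f]][2L] < cfg[[f]][1L])
      stop("`", f, "` must be a non-empty c(min, max) range")
  structure(cfg, class = "scene_config")
}

# Internal scene canvas: background image, plant color layer and mask kept
# in an environment mutated by the drawing primitives.
draw_disc <- function(env, r0, c0, rad_r, rad_c, col) {
  H <- nrow(env$mask); W <- ncol(env$mask)
  rr <- max(1L, floor(r0 - rad_r)):min(H, ceiling(r0 + rad_r))
  cc <- max(1L, floor(c0 - rad_c)):min(W, ceiling(c0 + rad_c))
  if (length(rr) == 0L || length(cc) == 0L) return(invisible())
  inside <- outer((rr - r0)^2 / rad_r^2, (cc - c0)^2 / rad_c^2, "+") <= 1
  if (!any(inside)) return(invisible())
  env$mask[rr, cc][inside] <- 1L
  for (ch in 1:3) {
    plane <- env$plant[, , ch]
    plane[rr, cc][inside] <- col[ch]
    env$plant[, , ch] <- plane
  }
  invisible()
}

# Capsule rasterization: every pixel center within `thickness` of the
# segment becomes plant, giving a stroke with rounded ends.
draw_segment <- function(env, r0, c0, r1, c1, thickness, col) {
  H <- nrow(env$mask); W <- ncol(env$mask)
  rad <- thickness
  rr <- max(1L, floor(min(r0, r1) - rad)):min(H, ceiling(max(r0, r1) + rad))
  cc <- max(1L, floor(min(c0, c1) - rad)):min(W, ceiling(max(c0, c1) + rad))
  if (length(rr) == 0L || length(cc) == 0L) return(invisible())
  pr <- matrix(rep(rr, length(cc)), length(rr))
  pc <- matrix(rep(cc, each = length(rr)), length(rr))
  vr <- r1 - r0; vc <- c1 - c0
  L2 <- vr^2 + vc^2
  tt <- if (L2 == 0) 0 else clip(((pr - r0) * vr + (pc - c0) * vc) / L2, 0, 1)
  d2 <- (pr - (r0 + tt * vr))^2 + (pc - (c0 + tt * vc))^2
  inside <- d2 <= rad^2
  if (!any(inside)) return(invisible())
  env$mask[rr, cc][inside] <- 1L
  for (ch in 1:3) {
    plane <- env$plant[, , ch]
    plane[rr, cc][inside] <- col[ch]
    env$plant[, , ch] <- plane
  }
  invisible()
}

pick_plant_color <- function(cfg) {
  rng <- if (cfg$stressed && runif(1) < cfg$stressed_fraction)
    cfg$stressed_hue_range else cfg$plant_hue_range
  hue <- runif(1, rng[1L], rng[2L]) / 360
  s <- runif(1, 0.45, 0.85)
  v <- runif(1, 0.35, 0.8)
  as.numeric(col2rgb(hsv(hue, s, v)))
}

draw_plant_side <- function(env, cfg) {
  H <- cfg$height; W <- cfg$width
  n_br <- if (cfg$n_branches[1L] == cfg$n_branches[2L]) cfg$n_branches[1L]
          else sample(cfg$n_branches[1L]:cfg$n_branches[2L], 1L)
  if (n_br == 0L) return(invisible())
  base_r <- H - round(runif(1, 6, 14))
  base_c <- W / 2 + runif(1, -W / 8, W / 8)
  stem_len <- runif(1, 0.35, 0.6) * H
  stem_col <- pick_plant_color(cfg)
  npts <- 12L
  rs <- base_r - seq(0, stem_len, length.out = npts)
  cs <- base_c + cumsum(c(0, rnorm(npts - 1L, 0, 2.5)))
  for (q in seq_len(npts - 1L))
    draw_segment(env, rs[q], cs[q], rs[q + 1L], cs[q + 1L],
                 runif(1, 2.8, 3.6), stem_col)
  for (b in seq_len(n_br)) {
    at <- runif(1, 0.25, 0.95)
    ai <- 1L + floor(at * (npts - 1L))
    r0 <- rs[ai]; c0 <- cs[ai]
    ang <- runif(1, -70, 70) * pi / 180           # from vertical
    blen <- runif(1, cfg$branch_length[1L], cfg$branch_length[2L])
    r1 <- r0 - blen * cos(ang)
    c1 <- c0 + blen * sin(ang)
    bcol <- pick_plant_color(cfg)
    draw_segment(env, r0, c0, r1, c1, runif(1, 1.8, 2.6), bcol)
    rad <- runif(1, cfg$leaf_blob_radius[1L], cfg$leaf_blob_radius[2L])
    draw_disc(env, r1, c1, rad, rad * runif(1, 0.6, 1), pick_plant_color(cfg))
    mid <- runif(1, 0.4, 0.8)
    draw_disc(env, r0 + mid * (r1 - r0), c0 + mid * (c1 - c0),
              rad * 0.7, rad * 0.6, pick_plant_color(cfg))
  }
  invisible()
}

draw_plant_top <- function(env, cfg) {
  H <- cfg$height; W <- cfg$width
  n_br <- if (cfg$n_branches[1L] == cfg$n_branches[2L]) cfg$n_branches[1L]
          else sample(cfg$n_branches[1L]:cfg$n_branches[2L], 1L)
  if (n_br == 0L) return(invisible())
  r0 <- H / 2 + runif(1, -H / 10, H / 10)
  c0 <- W / 2 + runif(1, -W / 10, W / 10)
  draw_disc(env, r0, c0, 6, 6, pick_plant_color(cfg))
  for (b in seq_len(n_br)) {
    ang <- runif(1, 0, 2 * pi)
    blen <- runif(1, cfg$branch_length[1L], cfg$branch_length[2L]) * 0.7
    r1 <- r0 + blen * sin(ang)
    c1 <- c0 + blen * cos(ang)
    draw_segment(env, r0, c0, r1, c1, runif(1, 1.8, 2.6),
                 pick_plant_color(cfg))
    rad <- runif(1, cfg$leaf_blob_radius[1L], cfg$leaf_blob_radius[2L])
    draw_disc(env, r1, c1, rad * 1.2, rad * 0.8, pick_plant_color(cfg))
    mid <- runif(1, 0.45, 0.8)
    draw_disc(env, r0 + mid * (r1 - r0), c0 + mid * (c1 - c0),
              rad * 0.7, rad * 0.6, pick_plant_color(cfg))
  }
  invisible()
}

# Pot / carrier distractors in terracotta, gray and dull blue tones, i.e.
# colors deliberately close to stressed-plant and shadow hues.
draw_distractors <- function(img, cfg) {
  H <- cfg$height; W <- cfg$width
  k <- if (cfg$distractor_count[1L] == cfg$distractor_count[2L])
    cfg$distractor_count[1L]
  else sample(cfg$distractor_count[1L]:cfg$distractor_count[2L], 1L)
  if (k == 0L) return(img)
  for (q in seq_len(k)) {
    col <- switch(sample(3L, 1L),
                  as.numeric(col2rgb(hsv(runif(1, 15, 42) / 360,
                                         runif(1, 0.45, 0.8),
                                         runif(1, 0.3, 0.65)))),  # terracotta/ochre
                  rep(runif(1, 60, 140), 3L),                      # gray carrier
                  as.numeric(col2rgb(hsv(runif(1, 200, 230) / 360,
                                         runif(1, 0.15, 0.35),
                                         runif(1, 0.3, 0.5)))))   # dull blue
    if (runif(1) < 0.6) {   # rectangle (pot / carrier edge)
      rh <- round(runif(1, 15, 50)); rw <- round(runif(1, 25, 80))
      r0 <- sample.int(max(H - rh, 1L), 1L)
      c0 <- sample.int(max(W - rw, 1L), 1L)
      for (ch in 1:3)
        img[r0:(r0 + rh - 1L), c0:(c0 + rw - 1L), ch] <-
          col[ch] + matrix(rnorm(rh * rw, 0, 2), rh, rw)
    } else {                # disc (pot rim seen from top)
      rad <- runif(1, 8, 30)
      r0 <- runif(1, rad, H - rad); c0 <- runif(1, rad, W - rad)
      rr <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
      cc <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
      inside <- outer((rr - r0)^2, (cc - c0)^2, "+") <= rad^2
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[rr, cc][inside] <- col[ch]
        img[, , ch] <- plane
      }
    }
  }
  img
}

#' Generate one synthetic greenhouse scene
#'
#' Renders the configured scene and returns the RGB image together with its
#' pixel-exact plant mask: the mask is precisely the set of pixels touched
#' by a plant drawing primitive (hard-edged rendering, no anti-aliased
#' half-labels), and neither shadow, distractors nor additive noise alter
#' it.  Identical seeds give bit-identical scenes.
#'
#' @param config A [scene_config()].
#' @return List with `image` (`H x W x 3` array, integer intensities in
#'   0..255) and `mask` (integer `H x W` matrix in `{0, 1}`).
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    H <- config$height; W <- config$width
    base <- config$background_base_color + rnorm(3L, 0, 6)
    theta <- runif(1, 0, 2 * pi)
    gx <- matrix(rep(seq_len(W) / W, each = H), H, W)
    gy <- matrix(rep(seq_len(H) / H, W), H, W)
    grad <- (cos(theta) * gx + sin(theta) * gy) *
      config$background_gradient_strength
    img <- array(0, c(H, W, 3L))
    for (ch in 1:3) img[, , ch] <- base[ch] + grad
    img <- draw_distractors(img, config)

    env <- new.env()
    env$mask <- matrix(0L, H, W)
    env$plant <- array(0, c(H, W, 3L))
    if (config$view == "side") draw_plant_side(env, config)
    else draw_plant_top(env, config)

    if (any(env$mask > 0L) && config$shadow_strength > 0) {
      sh <- env$mask
      shift <- function(m, dr, dc) {
        out <- matrix(0L, H, W)
        rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
        ok_r <- rs >= 1L & rs <= H; ok_c <- cs >= 1L & cs <= W
        out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
        out
      }
      sh <- pmax(shift(env$mask, 4L, 3L), shift(env$mask, 6L, 4L),
                 shift(env$mask, 3L, 2L))
      dark <- 1 - config$shadow_strength * (sh > 0L & env$mask == 0L)
      for (ch in 1:3) img[, , ch] <- img[, , ch] * dark
    }

    plant_px <- env$mask > 0L
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[plant_px] <- env$plant[, , ch][plant_px]
      img[, , ch] <- plane
    }
    img <- img + array(rnorm(H * W * 3L, 0, config$noise_sd), c(H, W, 3L))
    img <- round(clip(img, 0, 255))
    list(image = img, mask = env$mask)
  })
}

#' Generate a dataset of paired scenes
#'
#' Draws one derived seed per scene (so scenes are independent yet the
#' whole dataset is reproducible from `seed`) and records them in a
#' manifest.
#'
#' @param n Number of scenes (>= 1).
#' @param config A [scene_config()]; its `seed` field is ignored in favor
#'   of the derived per-scene seeds.
#' @param seed Integer seed for the dataset.
#' @return An object of class `scene_dataset`: list with `scenes` (each a
#'   list `image`/`mask`), `manifest` (data frame: `id`, `seed`, `height`,
#'   `width`, `view`, `stressed`) and `config`.
#' @export
generate_dataset <- function(n, config = scene_config(), seed = NULL) {
  stopifnot(is_count(n), n >= 1L)
  scene_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  scenes <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- scene_seeds[i]
    scenes[[i]] <- generate_scene(cfg_i)
  }
  manifest <- data.frame(
    id = sprintf("scene_%03d", seq_len(n)), seed = scene_seeds,
    height = config$height, width = config$width, view = config$view,
    stressed = config$stressed, stringsAsFactors = FALSE)
  structure(list(scenes = scenes, manifest = manifest, config = config),
            class = "scene_dataset")
}

#' @export
print.scene_dataset <- function(x, ...) {
  cat(sprintf("<scene_dataset> %d %s-view scenes, %d x %d px%s\n",
              length(x$scenes), x$config$view, x$config$height,
              x$config$width, if (x$config$stressed) " (stressed)" else ""))
  invisible(x)
}

#' Write a scene dataset to disk
#'
#' Writes `images/<id>.png`, `masks/<id>.png` and a JSON manifest holding
#' the per-scene seeds and the generator configuration, from which the
#' dataset can be regenerated exactly.
#'
#' @param dataset A `scene_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "scene_dataset"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$scenes)) {
    id <- dataset$manifest$id[i]
    write_image(dataset$scenes[[i]]$image,
                file.path(dir, "images", paste0(id, ".png")))
    write_mask(dataset$scenes[[i]]$mask,
               file.path(dir, "masks", paste0(id, ".png")))
  }
  cfg <- unclass(dataset$config)
  cfg$seed <- NULL
  jsonlite::write_json(list(manifest = dataset$manifest, config = cfg),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Regenerate a scene dataset from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_dataset()].
#' @return A `scene_dataset` identical to the one originally written.
#' @export
regenerate_dataset <- function(manifest_path) {
  spec <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- do.call(scene_config, spec$config[setdiff(names(spec$config),
                                                   c("seed"))])
  scenes <- vector("list", nrow(spec$manifest))
  for (i in seq_len(nrow(spec$manifest))) {
    cfg_i <- cfg
    cfg_i$seed <- spec$manifest$seed[i]
    scenes[[i]] <- generate_scene(cfg_i)
  }
  structure(list(scenes = scenes, manifest = spec$manifest, config = cfg),
            class = "scene_dataset")
}
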