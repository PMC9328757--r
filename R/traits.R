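# Whole-shoot phenotypic traits from a binary mask and its RGB image.
#
# The registry fixes 35 scalar traits in 4 groups (area, bounding box,
# convex hull, color statistics).  Geometry is computed over the union of
# all plant components; hue statistics are circular (mean resultant
# direction) with H in [0, 360).

trait_names <- function() {
  c("area.plant_area_px", "area.filled_area_px", "area.area_fraction",
    "area.component_count", "area.largest_component_area_px",
    "bbox.min_row", "bbox.min_col", "bbox.height_px", "bbox.width_px",
    "bbox.area_px", "bbox.aspect_ratio", "bbox.extent", "bbox.diagonal_px",
    "hull.area_px", "hull.solidity", "hull.perimeter_px",
    "hull.max_diameter_px",
    "color.mean_r", "color.sd_r", "color.median_r",
    "color.mean_g", "color.sd_g", "color.median_g",
    "color.mean_b", "color.sd_b", "color.median_b",
    "color.mean_h", "color.sd_h", "color.mean_s", "color.sd_s",
    "color.mean_v", "color.sd_v",
    "color.mean_excess_green", "color.mean_norm_green",
    "color.mean_brightness")
}

#' Registry of the 35 shoot traits
#'
#' @return Data frame with columns `name` and `group` (35 rows; groups
#'   `area`, `bbox`, `hull`, `color`).
#' @export
trait_registry <- function() {
  nm <- trait_names()
  data.frame(name = nm, group = sub("\\..*$", "", nm),
             stringsAsFactors = FALSE)
}

# Fill holes: background components (4-connectivity on the complement) that
# do not touch the image border are interior holes.
fill_holes <- function(mask) {
  bg <- matrix(as.integer(mask == 0L), nrow(mask), ncol(mask))
  lab <- cpp_label_components(bg, 4L)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- border[border > 0L]
  filled <- mask
  hole <- lab > 0L & !(lab %in% border)
  filled[hole] <- 1L
  filled
}

# Rasterize the filled convex hull of the plant pixels.  Pixel centers are
# integer (row, col) coordinates; a scanline even-odd fill of the hull
# polygon is unioned with the filled mask, which guarantees
# filled_area <= hull_area even at discretization boundaries.
hull_raster <- function(mask, filled) {
  pts <- which(mask > 0L, arr.ind = TRUE)   # (row, col)
  out <- filled
  if (nrow(pts) < 3L) return(list(mask = out, vertices = pts))
  h_idx <- chull(pts[, 2L], pts[, 1L])
  v <- pts[h_idx, , drop = FALSE]           # hull vertices, (row, col)
  if (nrow(v) >= 3L) {
    vr <- as.numeric(v[, 1L]); vc <- as.numeric(v[, 2L])
    nv <- length(vr)
    for (r in seq(min(vr), max(vr))) {
      xs <- numeric(0)
      for (e in seq_len(nv)) {
        r1 <- vr[e]; c1 <- vc[e]
        r2 <- vr[if (e == nv) 1L else e + 1L]
        c2 <- vc[if (e == nv) 1L else e + 1L]
        if (r1 == r2) {
          if (r1 == r) xs <- c(xs, c1, c2)   # horizontal hull edge on this row
          next
        }
        tt <- (r - r1) / (r2 - r1)
        if (tt >= 0 && tt <= 1) xs <- c(xs, c1 + tt * (c2 - c1))
      }
      if (length(xs) == 0L) next
      lo <- ceiling(min(xs) - 1e-9)
      hi <- floor(max(xs) + 1e-9)
      if (hi >= lo) out[r, lo:hi] <- 1L
    }
  }
  list(mask = out, vertices = v)
}

circular_hue_stats <- function(h_deg) {
  a <- h_deg * pi / 180
  cm <- mean(cos(a)); sm <- mean(sin(a))
  mean_h <- (atan2(sm, cm) %% (2 * pi)) * 180 / pi
  rbar <- min(sqrt(cm^2 + sm^2), 1)
  sd_h <- sqrt(-2 * log(max(rbar, 1e-12))) * 180 / pi
  c(mean = mean_h, sd = sd_h)
}

#' Compute the 35 shoot traits for one segmented image
#'
#' Traits are computed over the union of all plant components (whole
#' shoot).  For an empty mask all geometric traits are 0 and the color
#' traits are `NA`.  Definitions: `filled_area` fills interior holes;
#' `extent` is plant area over bounding-box area; `solidity` plant area
#' over convex-hull area; excess green is `2G - R - B`; normalized green
#' `G / (R + G + B)`; hue statistics are circular with H in degrees.
#'
#' @param mask Integer `H x W` binary mask.
#' @param image `H x W x 3` RGB array with intensities in 0..255.
#' @return Named numeric vector of length 35 (see [trait_registry()]).
#' @examples
#' m <- matrix(0L, 50, 50); m[10:19, 10:19] <- 1L
#' img <- array(0, c(50, 50, 3)); img[, , 2] <- 200
#' compute_traits(m, img)[c("area.plant_area_px", "hull.solidity")]
#' @export
compute_traits <- function(mask, image) {
  d <- dim(image)
  if (length(d) != 3L || !identical(dim(mask), d[1:2]))
    stop("mask and image dimensions must match")
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  out <- setNames(numeric(35L), trait_names())
  area <- sum(m)
  if (area == 0L) {
    out[] <- 0
    out[grep("^color\\.", names(out))] <- NA_real_
    return(out)
  }
  lab <- cpp_label_components(m, 8L)
  comp_sizes <- tabulate(lab[lab > 0L])
  filled <- fill_holes(m)
  hr <- hull_raster(m, filled)

  out["area.plant_area_px"] <- area
  out["area.filled_area_px"] <- sum(filled)
  out["area.area_fraction"] <- area / (d[1L] * d[2L])
  out["area.component_count"] <- length(comp_sizes)
  out["area.largest_component_area_px"] <- max(comp_sizes)

  px <- which(m > 0L, arr.ind = TRUE)
  rmin <- min(px[, 1L]); rmax <- max(px[, 1L])
  cmin <- min(px[, 2L]); cmax <- max(px[, 2L])
  bh <- rmax - rmin + 1L; bw <- cmax - cmin + 1L
  out["bbox.min_row"] <- rmin
  out["bbox.min_col"] <- cmin
  out["bbox.height_px"] <- bh
  out["bbox.width_px"] <- bw
  out["bbox.area_px"] <- bh * bw
  out["bbox.aspect_ratio"] <- bh / bw
  out["bbox.extent"] <- area / (bh * bw)
  out["bbox.diagonal_px"] <- sqrt(bh^2 + bw^2)

  hull_area <- sum(hr$mask)
  out["hull.area_px"] <- hull_area
  out["hull.solidity"] <- area / hull_area
  v <- hr$vertices
  if (nrow(v) >= 2L) {
    dm <- as.matrix(stats::dist(v))
    out["hull.max_diameter_px"] <- max(dm)
    if (nrow(v) >= 3L) {
      nx <- c(seq_len(nrow(v))[-1L], 1L)
      out["hull.perimeter_px"] <-
        sum(sqrt((v[, 1L] - v[nx, 1L])^2 + (v[, 2L] - v[nx, 2L])^2))
    } else {
      out["hull.perimeter_px"] <- 2 * max(dm)
    }
  } else {
    out["hull.max_diameter_px"] <- 0
    out["hull.perimeter_px"] <- 0
  }

  r <- image[, , 1L][m > 0L]
  g <- image[, , 2L][m > 0L]
  b <- image[, , 3L][m > 0L]
  out["color.mean_r"] <- mean(r); out["color.sd_r"] <- sd(r)
  out["color.median_r"] <- median(r)
  out["color.mean_g"] <- mean(g); out["color.sd_g"] <- sd(g)
  out["color.median_g"] <- median(g)
  out["color.mean_b"] <- mean(b); out["color.sd_b"] <- sd(b)
  out["color.median_b"] <- median(b)
  hsv_m <- rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  hs <- circular_hue_stats(hsv_m[1L, ] * 360)
  out["color.mean_h"] <- hs["mean"]
  out["color.sd_h"] <- hs["sd"]
  out["color.mean_s"] <- mean(hsv_m[2L, ]); out["color.sd_s"] <- sd(hsv_m[2L, ])
  out["color.mean_v"] <- mean(hsv_m[3L, ]); out["color.sd_v"] <- sd(hsv_m[3L, ])
  out["color.mean_excess_green"] <- mean(2 * g - r - b)
  denom <- r + g + b
  out["color.mean_norm_green"] <- mean(ifelse(denom > 0, g / denom, 1 / 3))
  out["color.mean_brightness"] <- mean(denom / 3)
  out
}

#' Tabulate trait records
#'
#' @param records List of named trait vectors from [compute_traits()].
#' @param ids Character identifiers, one per record (default `record_1`,
#'   ...).
#' @param out_csv Optional CSV output path.
#' @return Data frame with an `id` column followed by the 35 trait columns
#'   in registry order (header-only when `records` is empty).
#' @export
traits_to_table <- function(records, ids = NULL, out_csv = NULL) {
  nm <- trait_names()
  if (length(records) == 0L) {
    tab <- as.data.frame(setNames(
      c(list(character(0)), rep(list(numeric(0)), length(nm))),
      c("id", nm)), check.names = FALSE)
  } else {
    if (is.null(ids)) ids <- paste0("record_", seq_along(records))
    stopifnot(length(ids) == length(records))
    rows <- lapply(records, function(r) as.data.frame(as.list(r[nm]),
                                                      check.names = FALSE))
    tab <- cbind(data.frame(id = ids, stringsAsFactors = FALSE),
                 do.call(rbind, rows))
    rownames(tab) <- NULL
  }
  if (!is.null(out_csv)) write.csv(tab, out_csv, row.names = FALSE)
  tab
}
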