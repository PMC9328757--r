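# Reading and writing images, masks and probability maps.
# 8-bit RGB images go through the png / tiff / jpeg packages; masks are
# written as single-channel PNGs with values {0, 255}; probability maps as
# 16-bit TIFF.

#' Read an RGB image
#'
#' Reads a PNG, TIFF or JPEG file and returns an `H x W x 3` numeric array
#' of intensities in 0..255.  Grayscale images are replicated across the
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return `H x W x 3` numeric array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: ", ext)
  )
  if (is.null(dim(raw))) stop("could not read image: ", path)
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), dim = c(dim(raw), 3L))
  if (dim(raw)[3L] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  if (dim(raw)[3L] == 1L) raw <- array(rep(raw, 3L), dim = c(dim(raw)[1:2], 3L))
  round(raw * 255)
}

#' Write an RGB image
#'
#' @param image `H x W x 3` numeric array, intensities in 0..255 (or
#'   already in `[0, 1]`).
#' @param path Output path; format chosen from the extension
#'   (`.png`, `.tif(f)`, `.jpg`/`.jpeg`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  x <- clip(normalize_intensities(image), 0, 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(x, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    jpg  = ,
    jpeg = jpeg::writeJPEG(x, target = path, quality = 0.95),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Write a binary mask as a single-channel PNG
#'
#' Plant pixels are stored as 255, background as 0.
#'
#' @param mask `H x W` matrix with values in `{0, 1}`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask > 0), nrow(mask), ncol(mask)),
                target = path)
  invisible(path)
}

#' Read a binary mask
#'
#' Reads a mask image (any supported format); pixels above half intensity
#' become plant (1), the rest background (0).
#'
#' @param path Path to the mask image.
#' @return Integer `H x W` matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  m <- img[, , 1L]
  matrix(as.integer(m > 127), nrow(m), ncol(m))
}

#' Write a probability map as a 16-bit TIFF
#'
#' @param pmap `H x W` matrix of probabilities in `[0, 1]`.
#' @param path Output `.tif(f)` path.
#' @return `path`, invisibly.
#' @export
write_probability_map <- function(pmap, path) {
  tiff::writeTIFF(clip(pmap, 0, 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a probability map written by [write_probability_map()]
#'
#' @param path Path to the TIFF file.
#' @return `H x W` numeric matrix in `[0, 1]`.
#' @export
read_probability_map <- function(path) {
  raw <- tiff::readTIFF(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  raw
}
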