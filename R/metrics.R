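#' Dice coefficient between two binary masks
#'
#' `2 * sum(P * G) / (sum(P) + sum(G))`: 1 is a perfect segmentation, 0 a
#' completely false one.  When both masks are empty the masks agree on the
#' absence of any plant pixel and the coefficient is defined as 1 (the
#' ratio is otherwise 0/0).
#'
#' @param P,G Binary `H x W` masks (values 0/1) of equal dimensions.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' a <- matrix(0, 4, 4); a[1, 1:2] <- 1
#' b <- matrix(0, 4, 4); b[1, 1] <- 1
#' dice(a, b)  # 2 * 1 / (2 + 1)
#' @export
dice <- function(P, G) {
  if (!identical(dim(P), dim(G)))
    stop("masks must have identical dimensions")
  sp <- sum(P)
  sg <- sum(G)
  if (sp == 0 && sg == 0) return(1)
  2 * sum(P * G) / (sp + sg)
}

#' Pixel-averaged binary cross-entropy
#'
#' `-mean(g * log(p) + (1 - g) * log(1 - p))` with natural logarithms;
#' probabilities are clipped into `[clip, 1 - clip]` so exact 0/1
#' predictions stay finite.
#'
#' @param pred Probability map (values in `[0, 1]`), any dimensions.
#' @param gt Ground-truth mask (values 0/1) of the same dimensions.
#' @param clip Clipping epsilon (default `1e-7`).
#' @return Mean cross-entropy loss (non-negative).
#' @export
binary_cross_entropy <- function(pred, gt, clip = 1e-7) {
  if (!identical(dim(pred), dim(gt)))
    stop("prediction and ground truth must have identical dimensions")
  p <- pmin(pmax(pred, clip), 1 - clip)
  -mean(gt * log(p) + (1 - gt) * log(1 - p))
}

#' Evaluate predicted masks against ground truth on disk
#'
#' Pairs files by name between two directories of mask images, computes the
#' per-image Dice coefficient and binary cross-entropy, and appends a
#' summary row with the mean and standard deviation of both metrics.
#'
#' @param pred_dir Directory of predicted mask images.
#' @param gt_dir Directory of ground-truth mask images with matching file
#'   names.
#' @param out_csv Optional path; when given the table is also written as
#'   CSV.
#' @return A data frame with columns `file`, `dice`, `ce`; the last two
#'   rows hold the mean and SD summaries.
#' @export
evaluate_mask_dir <- function(pred_dir, gt_dir, out_csv = NULL) {
  files <- sort(list.files(pred_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no mask images found in ", pred_dir)
  rows <- lapply(files, function(f) {
    gt_path <- file.path(gt_dir, f)
    if (!file.exists(gt_path))
      stop("no ground-truth mask for ", f, " in ", gt_dir)
    p <- read_mask(file.path(pred_dir, f))
    g <- read_mask(gt_path)
    data.frame(file = f, dice = dice(p, g), ce = binary_cross_entropy(p, g),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  summary <- data.frame(
    file = c("mean", "sd"),
    dice = c(mean(tab$dice), sd(tab$dice)),
    ce = c(mean(tab$ce), sd(tab$ce)), stringsAsFactors = FALSE)
  out <- rbind(tab, summary)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
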