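# Hepatorenal gray-level steatosis index: the ratio of the mean gray level
# in a liver ROI to that in a kidney-parenchyma ROI on one B-mode image.

# Logical mask of pixels strictly inside a ROI. Rectangles are
# c(row0, col0, row1, col1), 0-based half-open; polygons are N x 2 matrices
# of (row, col) vertices in 0-based pixel coordinates (even-odd rule on
# pixel centres).
roi_mask <- function(image, roi) {
  h <- nrow(image); w <- ncol(image)
  mask <- matrix(FALSE, h, w)
  if (is.matrix(roi)) {
    ry <- roi[, 1L]; rx <- roi[, 2L]
    if (any(ry < 0) || any(ry > h) || any(rx < 0) || any(rx > w))
      stop_musecho("polygon ROI outside image", "musecho_roi_error")
    n <- nrow(roi)
    for (r in seq_len(h)) {
      py <- r - 0.5                      # pixel centre, 0-based coords
      xs <- numeric(0)
      j <- n
      for (i in seq_len(n)) {
        if ((ry[i] > py) != (ry[j] > py)) {
          xs <- c(xs, rx[i] + (py - ry[i]) / (ry[j] - ry[i]) * (rx[j] - rx[i]))
        }
        j <- i
      }
      if (length(xs)) {
        xs <- sort(xs)
        for (k in seq(1L, length(xs) - 1L, by = 2L)) {
          cols <- which(seq_len(w) - 0.5 > xs[k] & seq_len(w) - 0.5 < xs[k + 1L])
          mask[r, cols] <- TRUE
        }
      }
    }
  } else {
    stopifnot(length(roi) == 4L)
    if (roi[1L] < 0 || roi[2L] < 0 || roi[3L] > h || roi[4L] > w ||
        roi[3L] <= roi[1L] || roi[4L] <= roi[2L])
      stop_musecho("rectangle ROI outside image or degenerate",
                   "musecho_roi_error")
    mask[(roi[1L] + 1L):roi[3L], (roi[2L] + 1L):roi[4L]] <- TRUE
  }
  mask
}

#' Mean gray level inside a region of interest
#'
#' @param image numeric matrix, gray levels in `[0, 255]`.
#' @param roi rectangle `c(row0, col0, row1, col1)` (0-based, half-open) or
#'   an `N x 2` polygon of (row, col) vertices in 0-based pixel coordinates.
#' @param min_area minimum ROI pixel count (statistical-stability guard).
#' @return arithmetic mean of the pixels strictly inside the ROI.
#' @export
roi_mean <- function(image, roi, min_area = 100L) {
  mask <- roi_mask(image, roi)
  n <- sum(mask)
  if (n < min_area)
    stop_musecho(sprintf("ROI has %d px, below the minimum of %d", n, min_area),
                 "musecho_roi_error")
  mean(image[mask])
}

#' Liver-to-kidney gray-level ratio (steatosis index)
#'
#' The ratio of the mean liver gray level to the mean kidney-parenchyma gray
#' level on a single B-mode image, used as a surrogate index of hepatic
#' steatosis. No depth/TGC compensation is applied: the index is a raw
#' gray-level ratio.
#'
#' @param liver_mean mean liver gray level, or an image matrix when `liver`
#'   and `kidney` ROIs are given.
#' @param kidney_mean mean kidney gray level.
#' @param liver,kidney optional ROIs (see [roi_mean()]) when the first
#'   argument is an image.
#' @return list with `liver_mean`, `kidney_mean`, `steatoscore`.
#' @export
steatoscore <- function(liver_mean, kidney_mean = NULL, liver = NULL,
                        kidney = NULL) {
  if (is.matrix(liver_mean)) {
    img <- liver_mean
    if (is.null(liver) || is.null(kidney))
      stop_musecho("image input needs both liver and kidney ROIs",
                   "musecho_roi_error")
    lm_ <- roi_mean(img, liver)
    km_ <- roi_mean(img, kidney)
    ml <- roi_mask(img, liver); mk <- roi_mask(img, kidney)
    if (any(ml & mk))
      stop_musecho("liver and kidney ROIs overlap", "musecho_roi_error")
    liver_mean <- lm_; kidney_mean <- km_
  }
  if (kidney_mean <= 1e-6)
    stop_musecho("kidney mean is ~0: uninformative reference region",
                 "musecho_roi_error")
  list(liver_mean = liver_mean, kidney_mean = kidney_mean,
       steatoscore = liver_mean / kidney_mean)
}
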