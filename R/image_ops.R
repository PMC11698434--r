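#' Maximum-intensity projection of a confocal z-stack
#'
#' With `group_size = NULL` a single pixelwise-maximum projection over all
#' planes is returned. With a positive `group_size` g, one projection is
#' produced per consecutive block of g planes (the last block may be shorter)
#' — e.g. g = 5 reproduces "maximum projection every 5 stacks".
#'
#' @param stack numeric matrix (single plane) or 3D array `[row, col, plane]`.
#' @param group_size block size, or `NULL` for one projection over all planes.
#' @return a matrix, or a list of matrices when `group_size` is given.
#' @export
project_stack <- function(stack, group_size = NULL) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (length(dim(stack)) != 3L || dim(stack)[3] < 1L)
    stop("'stack' must be a matrix or a non-empty 3D array")
  proj <- function(planes) {
    out <- stack[, , planes[1L]]
    for (p in planes[-1L]) out <- pmax(out, stack[, , p])
    out
  }
  np <- dim(stack)[3]
  if (is.null(group_size)) return(proj(seq_len(np)))
  group_size <- as.integer(group_size)
  if (group_size < 1L) stop("'group_size' must be a positive integer")
  starts <- seq(1L, np, by = group_size)
  lapply(starts, function(s) proj(s:min(s + group_size - 1L, np)))
}

#' Subtract a background estimate taken from a square region
#'
#' The mean intensity over a `roi_size` x `roi_size` square region placed
#' outside the pattern of interest (e.g. the notum for a pouch reporter) is
#' subtracted from every pixel; negative results are clamped to 0.
#'
#' @param image numeric matrix.
#' @param roi_corner top-left corner of the square, as (x, y) = (col, row).
#' @param roi_size side length in pixels (default 30).
#' @return background-subtracted matrix.
#' @export
subtract_background <- function(image, roi_corner, roi_size = 30) {
  image <- as.matrix(image)
  x0 <- as.integer(roi_corner[1]); y0 <- as.integer(roi_corner[2])
  if (x0 < 1L || y0 < 1L || x0 + roi_size - 1L > ncol(image) ||
      y0 + roi_size - 1L > nrow(image))
    stop("background ROI extends outside the image")
  bg <- mean(image[y0:(y0 + roi_size - 1L), x0:(x0 + roi_size - 1L)])
  pmax(image - bg, 0)
}

#' Binarize a pattern at a fraction of its maximum intensity
#'
#' A pixel is foreground iff its intensity is strictly greater than
#' `fraction` times the image maximum; the default 0.20 thresholds at 20% of
#' the maximum pixel value in the pattern. With `invert = TRUE` the
#' complement is returned (pixels at or below threshold), which localizes
#' vein stripes from an intervein marker such as DSRF.
#'
#' @param image numeric matrix with a positive maximum.
#' @param fraction threshold fraction of the maximum (default 0.20).
#' @param invert return the inverse binarization.
#' @return 0/1 integer matrix of the same shape.
#' @export
binarize_pattern <- function(image, fraction = 0.20, invert = FALSE) {
  image <- as.matrix(image)
  mx <- max(image)
  if (!is.finite(mx) || mx <= 0)
    stop("image has no positive intensities; nothing to binarize")
  m <- (image > fraction * mx)
  if (invert) m <- !m
  mask <- matrix(as.integer(m), nrow(image), ncol(image))
  mask
}

#' Clean and smooth a binary mask
#'
#' Noise cleanup: connected components smaller than `min_component_px` pixels
#' are removed; optionally only the largest component is retained (ties break
#' deterministically to the component labeled first in scan order). Edges are
#' then smoothed with a `blur_kernel` x `blur_kernel` mean filter followed by
#' re-thresholding at 0.5. `min_component_px = 0` with `blur_kernel = 1`
#' is the identity.
#'
#' @param mask 0/1 matrix.
#' @param min_component_px minimum component size kept (default 64).
#' @param blur_kernel odd side length of the mean filter (default 5).
#' @param keep_largest keep only the largest connected component.
#' @return cleaned 0/1 matrix.
#' @export
preprocess_mask <- function(mask, min_component_px = 64, blur_kernel = 5,
                            keep_largest = FALSE) {
  mask <- as.matrix(mask)
  if (any(mask > 0)) {
    lab <- EBImage::bwlabel(mask > 0)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_px)
    if (keep_largest && length(keep))
      keep <- keep[which.max(sizes[keep])]   # first-labeled wins ties
    mask <- matrix(as.integer(lab %in% keep & lab > 0), nrow(mask), ncol(mask))
  }
  blur_kernel <- as.integer(blur_kernel)
  if (blur_kernel > 1L) {
    kern <- matrix(1 / blur_kernel^2, blur_kernel, blur_kernel)
    sm <- EBImage::filter2(mask + 0, kern, boundary = 0)
    mask <- matrix(as.integer(sm > 0.5), nrow(mask), ncol(mask))
  }
  if (!any(mask > 0))
    stop("mask is empty after cleanup")
  mask
}

#' Foreground pixel coordinates of a mask
#'
#' @param mask 0/1 matrix.
#' @return n x 2 matrix of (x, y) = (col, row) coordinates of foreground
#'   pixels.
#' @export
mask_coords <- function(mask) {
  idx <- which(as.matrix(mask) > 0, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

#' Convex hull of a binary pattern
#'
#' Vertices of the smallest convex polygon enclosing all foreground pixel
#' coordinates, returned counterclockwise (positive shoelace orientation in
#' the x/y coordinates as stored). Interior pixels do not affect the hull.
#'
#' @param mask 0/1 matrix with at least 3 non-collinear foreground pixels.
#' @return m x 2 matrix of hull vertices (x, y).
#' @export
hull_points <- function(mask) {
  pts <- mask_coords(mask)
  if (nrow(pts) < 3L)
    stop("convex hull needs at least 3 foreground pixels")
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) < 3L)
    stop("foreground pixels are collinear; hull is degenerate")
  if (signed_loop_area(hp) < 0) hp <- hp[rev(seq_len(nrow(hp))), , drop = FALSE]
  hp
}

#' Eccentricity of a pattern via convex-envelope ellipse fitting
#'
#' Composition of [preprocess_mask()], [hull_points()] and [fit_ellipse()]:
#' the binarized pattern is cleaned and smoothed, its convex envelope is
#' taken, and an ellipse is least-squares fitted to the hull vertices. The
#' eccentricity `e = sqrt(1 - b^2/a^2)` of the fit quantifies pattern
#' roundness (0 = circle).
#'
#' @param mask 0/1 pattern mask.
#' @param min_component_px,blur_kernel,keep_largest passed to
#'   [preprocess_mask()]; by default only the largest component is kept.
#' @return a `fitted_ellipse`.
#' @export
pattern_eccentricity <- function(mask, min_component_px = 64, blur_kernel = 5,
                                 keep_largest = TRUE) {
  m <- preprocess_mask(mask, min_component_px = min_component_px,
                       blur_kernel = blur_kernel, keep_largest = keep_largest)
  fit_ellipse(hull_points(m))
}

#' Estimate overlapping nuclei from two pattern masks
#'
#' The number of pixels set in both masks divided by the nominal nuclear
#' area in pixels (default 200) estimates how many nuclei express both
#' patterns. The estimate is fractional, not rounded, and symmetric in its
#' arguments.
#'
#' @param mask_a,mask_b 0/1 matrices of equal shape.
#' @param nucleus_px pixel area of one nucleus (default 200).
#' @return non-negative scalar estimate.
#' @export
overlap_nuclei_estimate <- function(mask_a, mask_b, nucleus_px = 200) {
  mask_a <- as.matrix(mask_a); mask_b <- as.matrix(mask_b)
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks differ in shape")
  if (nucleus_px <= 0) stop("'nucleus_px' must be positive")
  sum(mask_a > 0 & mask_b > 0) / nucleus_px
}
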