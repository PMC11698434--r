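#' Read an intensity image or z-stack
#'
#' TIFF (single- or multi-plane) and PNG are supported. The result is a
#' numeric matrix `[row, col]` for a single plane or a 3D array
#' `[row, col, plane]` for a stack. Multi-channel PNG input is reduced to its
#' first channel with a warning.
#'
#' @param path image file (`.tif`, `.tiff`, `.png`).
#' @return numeric matrix or 3D array of intensities as stored in the file.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(planes)) planes <- list(planes)
    planes <- lapply(planes, drop_channels)
    if (length(planes) == 1L) return(planes[[1L]])
    array(unlist(planes), dim = c(dim(planes[[1L]]), length(planes)))
  } else if (grepl("\\.png$", path, ignore.case = TRUE)) {
    drop_channels(png::readPNG(path))
  } else stop("unsupported image format: ", path)
}

drop_channels <- function(img) {
  if (length(dim(img)) == 3L) {
    warning("multi-channel image reduced to its first channel")
    img <- img[, , 1L]
  }
  img
}

#' Write a binary mask as a PNG file
#'
#' @param mask 0/1 matrix.
#' @param path output `.png` path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((as.matrix(mask) > 0) + 0, path)
  invisible(NULL)
}
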