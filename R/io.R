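#' Read a TIFF image as a numeric matrix (or stack)
#'
#' Single-plane images return a numeric matrix; multi-frame TIFFs return a
#' 3D array `(row, col, frame)`; two-channel planes return an array
#' `(row, col, channel)`. Integer sample values are preserved (`as.is`),
#' falling back to the normalised unit-interval representation for float
#' TIFFs.
#'
#' @param path TIFF file path.
#' @return Numeric matrix or array.
#' @export
read_image <- function(path) {
  x <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  first_plane <- function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p
  }
  if (length(x) == 1) {
    p <- x[[1]]
    if (length(dim(p)) == 3) array(as.numeric(p), dim(p))
    else matrix(as.numeric(p), nrow(p), ncol(p))
  } else {
    arr <- array(0, c(dim(x[[1]])[1:2], length(x)))
    for (i in seq_along(x)) arr[, , i] <- first_plane(x[[i]])
    arr
  }
}

#' Write a numeric matrix (or stack) as 16-bit TIFF
#'
#' Values are clamped to `[0, 65535]` and written as integer samples; a 3D
#' array is written as a multi-frame TIFF.
#'
#' @param image Numeric matrix or `(row, col, frame)` array.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  scale <- 65535
  to_plane <- function(m) pmin(pmax(m, 0), scale) / scale
  if (length(dim(image)) == 3) {
    planes <- lapply(seq_len(dim(image)[3]), function(i) to_plane(image[, , i]))
    tiff::writeTIFF(planes, path, bits.per.sample = 16)
  } else {
    tiff::writeTIFF(to_plane(image), path, bits.per.sample = 16)
  }
  invisible(path)
}
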