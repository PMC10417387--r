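#' RGB image containers and input/output
#'
#' Images are plain numeric arrays of dimension `height x width x 3` with
#' channel values in `[0, 1]` (8-bit sources are divided by 255 on read).
#' This is the unit every pipeline stage exchanges.
#'
#' @param x numeric array `H x W x 3`.
#' @return `rgb_image()` returns its validated input.
#' @export
rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("an rgb image must be a numeric H x W x 3 array")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("image height and width must be at least 1")
  if (anyNA(x) || min(x) < 0 || max(x) > 1)
    stop("rgb channel values must lie in [0, 1]")
  storage.mode(x) <- "double"
  x
}

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L &&
    !anyNA(x) && min(x) >= 0 && max(x) <= 1
}

# EBImage stores pixels as (x = column, y = row, channel); convert both ways.
as_ebimage <- function(x) {
  if (length(dim(x)) == 2L) EBImage::Image(t(x))
  else EBImage::Image(aperm(x, c(2L, 1L, 3L)), colormode = EBImage::Color)
}

from_ebimage <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
}

#' Read and write 8-bit RGB images
#'
#' PNG and JPEG are supported on read; output is always written as PNG to
#' avoid recompression loss. Grayscale files are expanded to three equal
#' channels.
#'
#' @param path file path.
#' @return `read_image()` returns an [rgb_image()] array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3] > 3L) d <- d[, , 1:3, drop = FALSE]  # drop alpha
  rgb_image(clamp01(aperm(d, c(2L, 1L, 3L))))
}

#' @param image an [rgb_image()] array.
#' @rdname read_image
#' @export
write_image <- function(image, path) {
  image <- rgb_image(image)
  EBImage::writeImage(as_ebimage(image), path, type = "png")
  invisible(path)
}

#' Bilinear resize to a square target
#'
#' All dermoscopy inputs are brought to one square working geometry
#' (default 512 in the full pipeline) by bilinear interpolation; values are
#' clamped back to `[0, 1]` after filtering.
#'
#' @param image an [rgb_image()] array.
#' @param target output side length in pixels.
#' @return `target x target x 3` [rgb_image()].
#' @export
resize_image <- function(image, target) {
  image <- rgb_image(image)
  target <- as.integer(target)
  if (target < 1L) stop("target size must be positive")
  if (dim(image)[1] == target && dim(image)[2] == target) return(image)
  out <- EBImage::resize(as_ebimage(image), w = target, h = target,
                         filter = "bilinear")
  rgb_image(clamp01(from_ebimage(out)))
}

# Center crop retaining `fraction` of each side (used for the optional
# dominant-region selection before enhancement).
center_crop <- function(image, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  d <- dim(image)
  h <- max(1L, round(d[1] * fraction))
  w <- max(1L, round(d[2] * fraction))
  r0 <- (d[1] - h) %/% 2L
  c0 <- (d[2] - w) %/% 2L
  image[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w), , drop = FALSE]
}
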