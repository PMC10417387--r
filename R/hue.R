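#' Hue of RGB pixels
#'
#' The geometric hue angle of a pixel `p = (r, g, b)`, defined as 0 for
#' achromatic pixels (`r = g = b`), and otherwise as
#' `theta = arccos( ((r-g) + (r-b)) / 2 / sqrt((r-g)^2 + (r-b)(g-b)) )`
#' with the reflection `2*pi - theta` taken when `b > g`. This is the
#' quantity the hue-preserving enhancement keeps invariant: any map of the
#' form `x -> a*x + t*(1,1,1)` with `a > 0` leaves it unchanged.
#'
#' @param r,g,b numeric vectors of channel values in `[0, 1]` (recycled to
#'   a common length).
#' @param epsilon channel spread below which a pixel is treated as
#'   achromatic (guards the arccos against round-off instability).
#' @return hue angles in radians, in `[0, 2*pi)`.
#' @export
compute_hue <- function(r, g, b, epsilon = 1e-9) {
  n <- max(length(r), length(g), length(b))
  r <- rep_len(as.numeric(r), n)
  g <- rep_len(as.numeric(g), n)
  b <- rep_len(as.numeric(b), n)
  spread <- pmax(r, g, b) - pmin(r, g, b)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  ratio <- ifelse(den > 0, num / den, 1)
  ratio <- pmin(1, pmax(-1, ratio))
  theta <- acos(ratio)
  h <- ifelse(b > g, 2 * pi - theta, theta)
  h[spread < epsilon] <- 0
  h
}

# Hue of every pixel of an H x W x 3 image, as an H x W matrix.
image_hue <- function(image, epsilon = 1e-9) {
  d <- dim(image)
  matrix(compute_hue(image[, , 1], image[, , 2], image[, , 3], epsilon),
         d[1], d[2])
}
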