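#' CIECAM02 colour appearance model
#'
#' Forward and inverse CIECAM02 transforms, used to obtain perceptual
#' lightness J, chroma C and hue angle h for every pixel of a dermoscopy
#' image. The model takes a set of viewing conditions: the adopted white
#' point, the adapting field luminance `la` (cd/m^2), the relative
#' background luminance factor `yb`, and a surround category which fixes
#' the `(f, c, nc)` triple.
#'
#' @param white_xyz XYZ tristimulus of the adopted white, on the 0-100
#'   scale (default D65).
#' @param la adapting luminance in cd/m^2.
#' @param yb background relative luminance factor (percent of white).
#' @param surround one of `"average"`, `"dim"`, `"dark"`.
#' @param discount_illuminant assume complete chromatic adaptation to the
#'   white (degree of adaptation D = 1). The default, appropriate for
#'   display-referred imagery, maps the white point to zero chroma; set
#'   `FALSE` for the luminance-dependent D of the standard model.
#' @return a viewing-conditions record with the derived model constants.
#' @export
ciecam02_viewing <- function(white_xyz = c(95.047, 100.00001, 108.883),
                             la = 64, yb = 20,
                             surround = c("average", "dim", "dark"),
                             discount_illuminant = TRUE) {
  surround <- match.arg(surround)
  if (la <= 0 || yb <= 0) stop("viewing luminances must be positive")
  sur <- switch(surround,
                average = c(f = 1.0, c = 0.69,  nc = 1.0),
                dim     = c(f = 0.9, c = 0.59,  nc = 0.9),
                dark    = c(f = 0.8, c = 0.525, nc = 0.8))
  vc <- list(white_xyz = white_xyz, la = la, yb = yb, surround = surround,
             f = sur[["f"]], c = sur[["c"]], nc = sur[["nc"]])

  m02 <- matrix(c(0.7328, 0.4296, -0.1624,
                  -0.7036, 1.6975, 0.0061,
                  0.0030, 0.0136, 0.9834), 3, 3, byrow = TRUE)
  mhpe <- matrix(c(0.38971, 0.68898, -0.07868,
                   -0.22981, 1.18340, 0.04641,
                   0, 0, 1), 3, 3, byrow = TRUE)
  vc$m02 <- m02
  vc$m02_inv <- solve(m02)
  vc$mhpe <- mhpe
  vc$mhpe_inv <- solve(mhpe)

  rgb_w <- as.vector(m02 %*% white_xyz)
  d <- if (isTRUE(discount_illuminant)) 1
       else vc$f * (1 - (1 / 3.6) * exp((-la - 42) / 92))
  vc$d <- min(1, max(0, d))
  vc$d_rgb <- vc$d * white_xyz[2] / rgb_w + 1 - vc$d

  k <- 1 / (5 * la + 1)
  vc$fl <- 0.2 * k^4 * (5 * la) + 0.1 * (1 - k^4)^2 * (5 * la)^(1 / 3)
  vc$n <- yb / white_xyz[2]
  vc$nbb <- vc$ncb <- 0.725 * (1 / vc$n)^0.2
  vc$z <- 1.48 + sqrt(vc$n)

  rgb_wc <- vc$d_rgb * rgb_w
  rgbp_w <- as.vector(vc$mhpe %*% (vc$m02_inv %*% rgb_wc))
  rgba_w <- cam02_adapt(rgbp_w, vc$fl)
  vc$aw <- (2 * rgba_w[1] + rgba_w[2] + rgba_w[3] / 20 - 0.305) * vc$nbb
  class(vc) <- "ciecam02_viewing"
  vc
}

# post-adaptation nonlinear compression (sign-symmetric for negatives)
cam02_adapt <- function(x, fl) {
  t <- (fl * abs(x) / 100)^0.42
  sign(x) * 400 * t / (t + 27.13) + 0.1
}

cam02_adapt_inv <- function(xa, fl) {
  y <- xa - 0.1
  t <- 27.13 * abs(y) / (400 - abs(y))
  sign(y) * (100 / fl) * t^(1 / 0.42)
}

#' @describeIn ciecam02_viewing forward model. `xyz` is a `3 x n` matrix
#'   (0-100 scale); returns a list with vectors `J` (0-100), `C` and `h`
#'   (degrees in `[0, 360)`).
#' @param xyz `3 x n` matrix of tristimulus values.
#' @param vc viewing conditions from `ciecam02_viewing()`.
#' @export
ciecam02_forward <- function(xyz, vc) {
  xyz <- as.matrix(xyz)
  rgb <- vc$m02 %*% xyz
  rgb_c <- rgb * vc$d_rgb
  rgbp <- vc$mhpe %*% (vc$m02_inv %*% rgb_c)
  rgba <- cam02_adapt(rgbp, vc$fl)

  ra <- rgba[1, ]; ga <- rgba[2, ]; ba <- rgba[3, ]
  a <- ra - 12 * ga / 11 + ba / 11
  b <- (ra + ga - 2 * ba) / 9
  h <- (atan2(b, a) * 180 / pi) %% 360
  et <- 0.25 * (cos(h * pi / 180 + 2) + 3.8)
  aa <- (2 * ra + ga + ba / 20 - 0.305) * vc$nbb
  jj <- 100 * (pmax(aa, 0) / vc$aw)^(vc$c * vc$z)
  t <- (50000 / 13 * vc$nc * vc$ncb * et * sqrt(a^2 + b^2)) /
    (ra + ga + 21 / 20 * ba)
  cc <- t^0.9 * sqrt(jj / 100) * (1.64 - 0.29^vc$n)^0.73
  list(J = jj, C = cc, h = h)
}

#' @describeIn ciecam02_viewing inverse model: recovers a `3 x n` XYZ
#'   matrix from `J`, `C`, `h` vectors.
#' @param J,C,h CIECAM02 correlates as returned by the forward model.
#' @export
ciecam02_inverse <- function(J, C, h, vc) {
  t <- (C / (sqrt(pmax(J, 0) / 100) * (1.64 - 0.29^vc$n)^0.73))^(1 / 0.9)
  t[!is.finite(t)] <- 0
  et <- 0.25 * (cos(h * pi / 180 + 2) + 3.8)
  aa <- vc$aw * (pmax(J, 0) / 100)^(1 / (vc$c * vc$z))
  p1 <- (50000 / 13 * vc$nc * vc$ncb) * et / t
  p2 <- aa / vc$nbb + 0.305
  p3 <- 21 / 20
  hr <- h * pi / 180
  sh <- sin(hr); ch <- cos(hr)

  a <- numeric(length(J)); b <- numeric(length(J))
  nz <- is.finite(p1) & t > 1e-12
  s_dom <- nz & (abs(sh) >= abs(ch))
  c_dom <- nz & !s_dom
  if (any(s_dom)) {
    p4 <- p1[s_dom] / sh[s_dom]
    b[s_dom] <- p2[s_dom] * (2 + p3) * (460 / 1403) /
      (p4 + (2 + p3) * (220 / 1403) * (ch[s_dom] / sh[s_dom]) -
         (27 / 1403) + p3 * (6300 / 1403))
    a[s_dom] <- b[s_dom] * ch[s_dom] / sh[s_dom]
  }
  if (any(c_dom)) {
    p5 <- p1[c_dom] / ch[c_dom]
    a[c_dom] <- p2[c_dom] * (2 + p3) * (460 / 1403) /
      (p5 + (2 + p3) * (220 / 1403) -
         ((27 / 1403) - p3 * (6300 / 1403)) * (sh[c_dom] / ch[c_dom]))
    b[c_dom] <- a[c_dom] * sh[c_dom] / ch[c_dom]
  }

  ra <- (460 * p2 + 451 * a + 288 * b) / 1403
  ga <- (460 * p2 - 891 * a - 261 * b) / 1403
  ba <- (460 * p2 - 220 * a - 6300 * b) / 1403
  rgbp <- rbind(cam02_adapt_inv(ra, vc$fl),
                cam02_adapt_inv(ga, vc$fl),
                cam02_adapt_inv(ba, vc$fl))
  rgb_c <- vc$m02 %*% (vc$mhpe_inv %*% rgbp)
  rgb <- rgb_c / vc$d_rgb
  vc$m02_inv %*% rgb
}

# sRGB (D65) <-> XYZ on the 0-100 scale
srgb_to_xyz <- function(rgb) {
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  100 * (m %*% lin)
}

xyz_to_srgb <- function(xyz) {
  m <- matrix(c(3.2404542, -1.5371385, -0.4985314,
                -0.9692660, 1.8760108, 0.0415560,
                0.0556434, -0.2040259, 1.0572252), 3, 3, byrow = TRUE)
  lin <- m %*% (xyz / 100)
  ifelse(lin <= 0.0031308, 12.92 * lin,
         1.055 * pmax(lin, 0)^(1 / 2.4) - 0.055)
}

#' Convert an RGB image to CIECAM02 JCh planes
#'
#' Runs the forward CIECAM02 model on every pixel and returns the
#' lightness, chroma and hue planes together with their normalized
#' counterparts. `J` and `C` planes are stored on the model's native
#' 0-100 scale; the normalized planes divide the unit-scaled lightness
#' and chroma by 0.43 and the hue (degrees) by 15, the weighting that
#' emphasizes hue relative to the other correlates.
#'
#' @param image an [rgb_image()] array; pixels are interpreted as sRGB.
#' @param viewing conditions from [ciecam02_viewing()].
#' @return object of class `jch_image` with matrices `J_plane`, `C_plane`,
#'   `h_plane`, `Jn_plane`, `Cn_plane`, `hn_plane`.
#' @export
rgb_to_jch <- function(image, viewing = ciecam02_viewing()) {
  image <- rgb_image(image)
  if (!inherits(viewing, "ciecam02_viewing"))
    stop("viewing must be created by ciecam02_viewing()")
  d <- dim(image)
  px <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  out <- ciecam02_forward(srgb_to_xyz(px), viewing)
  shape <- function(v) matrix(v, d[1], d[2])
  res <- list(J_plane = shape(out$J), C_plane = shape(out$C),
              h_plane = shape(out$h %% 360),
              Jn_plane = shape(out$J / 100 / 0.43),
              Cn_plane = shape(out$C / 100 / 0.43),
              hn_plane = shape((out$h %% 360) / 15),
              viewing_conditions = viewing)
  class(res) <- "jch_image"
  res
}

#' @describeIn rgb_to_jch inverse mapping from a `jch_image` back to an
#'   sRGB array (values clamped to `[0, 1]`).
#' @param jch a `jch_image`.
#' @export
jch_to_rgb <- function(jch) {
  stopifnot(inherits(jch, "jch_image"))
  vc <- jch$viewing_conditions
  xyz <- ciecam02_inverse(as.vector(jch$J_plane), as.vector(jch$C_plane),
                          as.vector(jch$h_plane), vc)
  rgb <- clamp01(xyz_to_srgb(xyz))
  d <- dim(jch$J_plane)
  out <- array(0, c(d[1], d[2], 3))
  for (ch in 1:3) out[, , ch] <- matrix(rgb[ch, ], d[1], d[2])
  rgb_image(out)
}
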