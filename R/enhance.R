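#' Configuration for hue-preserving contrast enhancement
#'
#' Tunables for [enhance_image()] and its stages. The global map is a
#' sigmoid on the intensity plane with slope `sigmoid_gain` and midpoint
#' `sigmoid_cutoff`; the local map is contrast-limited tile-wise histogram
#' equalization (CLAHE) over a `tile_grid[1] x tile_grid[2]` grid with
#' clip factor `clip_limit`. The two are fused per pixel, either with a
#' fixed weight or with a weight driven by local contrast and brightness.
#'
#' @param sigmoid_gain positive slope of the global sigmoid.
#' @param sigmoid_cutoff sigmoid midpoint on the `[0, 1]` intensity scale.
#' @param tile_grid integer pair: CLAHE tiles along rows and columns.
#' @param clip_limit positive CLAHE clip factor.
#' @param fusion_weight_mode `"contrast_brightness"` (per-pixel weight) or
#'   `"fixed"`.
#' @param fixed_weight global-map weight in `[0, 1]` when mode is
#'   `"fixed"`.
#' @param hue_epsilon channel spread treated as achromatic (see
#'   [compute_hue()]).
#' @param roi_mode `"none"` or `"center_crop"` dominant-region selection.
#' @param roi_fraction side fraction retained by the center crop.
#' @return a list of class `enhance_config`.
#' @export
enhance_config <- function(sigmoid_gain = 8, sigmoid_cutoff = 0.5,
                           tile_grid = c(8L, 8L), clip_limit = 2,
                           fusion_weight_mode = c("contrast_brightness",
                                                  "fixed"),
                           fixed_weight = 0.5, hue_epsilon = 1e-9,
                           roi_mode = c("none", "center_crop"),
                           roi_fraction = 0.8) {
  fusion_weight_mode <- match.arg(fusion_weight_mode)
  roi_mode <- match.arg(roi_mode)
  if (sigmoid_gain <= 0) stop("sigmoid_gain must be positive")
  if (fixed_weight < 0 || fixed_weight > 1)
    stop("fixed_weight must lie in [0, 1]")
  if (clip_limit <= 0) stop("clip_limit must be positive")
  if (roi_fraction <= 0 || roi_fraction > 1)
    stop("roi_fraction must lie in (0, 1]")
  structure(list(sigmoid_gain = sigmoid_gain,
                 sigmoid_cutoff = sigmoid_cutoff,
                 tile_grid = as.integer(tile_grid),
                 clip_limit = clip_limit,
                 fusion_weight_mode = fusion_weight_mode,
                 fixed_weight = fixed_weight,
                 hue_epsilon = hue_epsilon,
                 roi_mode = roi_mode,
                 roi_fraction = roi_fraction),
            class = "enhance_config")
}

#' Global min-max stretch
#'
#' Translates the pixel values of a colour image to the full `[0, 1]`
#' range: `X' = (X - Xmin) / (Xmax - Xmin)`, where `Xmin` and `Xmax` are
#' the global extrema over all three channels. A constant image has no
#' contrast to stretch; it is mapped to all zeros with a warning so batch
#' preprocessing survives blank frames.
#'
#' @param image an [rgb_image()] array.
#' @return stretched [rgb_image()].
#' @export
global_stretch <- function(image) {
  image <- rgb_image(image)
  lo <- min(image); hi <- max(image)
  if (hi <= lo) {
    warning("constant image: min-max stretch is degenerate, returning zeros")
    return(rgb_image(array(0, dim(image))))
  }
  rgb_image((image - lo) / (hi - lo))
}

#' Luma intensity plane
#'
#' Per-pixel weighted channel sum `0.299 R + 0.587 G + 0.114 B` (the
#' Rec. 601 luma weights, which sum to 1 so gray pixels keep their value).
#'
#' @param image an [rgb_image()] array.
#' @return `H x W` matrix of intensities in `[0, 1]`.
#' @export
rgb_to_intensity <- function(image) {
  image <- rgb_image(image)
  J <- image[, , 1] * 0.299 + image[, , 2] * 0.587 + image[, , 3] * 0.114
  matrix(J, dim(image)[1], dim(image)[2])
}

# Global sigmoid map, rescaled over the [0, 1] domain endpoints so the
# output spans [0, 1] regardless of the data, stays monotone, and equals
# 0.5 at the cutoff when the cutoff is centered.
sigmoid_global_map <- function(J, gain, cutoff) {
  sig <- function(x) 1 / (1 + exp(-gain * (x - cutoff)))
  s0 <- sig(0); s1 <- sig(1)
  (sig(J) - s0) / (s1 - s0)
}

#' Enhanced intensity plane
#'
#' Fuses a global sigmoid contrast map with local contrast-limited
#' histogram equalization of the intensity plane:
#' `GI = w * G_global + (1 - w) * G_local`. The hue plane accompanies the
#' intensity plane through the pipeline (the JCh decomposition drives the
#' enhancement's perceptual framing); the local equalization itself
#' operates on intensity tiles. With a constant intensity plane there is
#' no local contrast and `G_local` falls back to `G_global`.
#'
#' @param J `H x W` intensity matrix in `[0, 1]` (see
#'   [rgb_to_intensity()]).
#' @param h_plane `H x W` hue plane from [rgb_to_jch()] (may be `NULL`).
#' @param config an [enhance_config()].
#' @return `H x W` matrix `GI` with values in `[0, 1]`.
#' @export
enhance_intensity <- function(J, h_plane = NULL, config = enhance_config()) {
  stopifnot(is.matrix(J))
  d <- dim(J)
  if (config$tile_grid[1] > d[1])
    stop("tile_grid rows (", config$tile_grid[1],
         ") exceed image height (", d[1], ")")
  if (config$tile_grid[2] > d[2])
    stop("tile_grid cols (", config$tile_grid[2],
         ") exceed image width (", d[2], ")")

  g_global <- sigmoid_global_map(J, config$sigmoid_gain,
                                 config$sigmoid_cutoff)
  if (max(J) - min(J) < 1e-12) {
    g_local <- g_global
  } else {
    g_local <- clamp01(from_ebimage(
      EBImage::clahe(as_ebimage(J),
                     nx = config$tile_grid[2], ny = config$tile_grid[1],
                     limit = config$clip_limit)))
  }

  if (config$fusion_weight_mode == "fixed") {
    w <- config$fixed_weight
  } else {
    # local RMS contrast (5x5 box) normalized to [0, 1], averaged with a
    # brightness term that down-weights the global map at the extremes
    br <- EBImage::makeBrush(5, shape = "box")
    br <- br / sum(br)
    mu <- from_ebimage(EBImage::filter2(as_ebimage(J), br))
    mu2 <- from_ebimage(EBImage::filter2(as_ebimage(J * J), br))
    rms <- sqrt(pmax(mu2 - mu^2, 0))
    cn <- if (max(rms) > 0) rms / max(rms) else rms
    bl <- 1 - 2 * abs(J - 0.5)
    w <- clamp01((cn + bl) / 2)
  }
  clamp01(w * g_global + (1 - w) * g_local)
}

#' Hue-preserving colour reconstruction
#'
#' Rebuilds an enhanced colour image from the stretched input `X'`, its
#' intensity plane `J` and the enhanced intensity `GI`, pixel by pixel:
#' when `GI/J <= 1` every channel is scaled by `GI/J`; otherwise the
#' shift-then-scale form `((1-GI)/(1-J)) * (X' - J) + GI` is used. Both
#' branches are of the hue-invariant form `a*x + t*(1,1,1)` with `a > 0`,
#' so the hue of every pixel is unchanged, and the branches agree at
#' `GI = J`. `J` is floored at `1e-6` before division so zero-intensity
#' pixels remain defined.
#'
#' @param stretched stretched [rgb_image()] (`X'`).
#' @param J intensity plane of `stretched`.
#' @param GI enhanced intensity plane, values in `[0, 1]`.
#' @return enhanced [rgb_image()].
#' @export
hue_preserving_reconstruct <- function(stretched, J, GI) {
  stretched <- rgb_image(stretched)
  d <- dim(stretched)
  stopifnot(identical(dim(J), d[1:2]), identical(dim(GI), d[1:2]))
  if (min(J) < 0 || max(J) > 1 || min(GI) < 0 || max(GI) > 1)
    stop("J and GI must lie in [0, 1]")
  Jf <- pmax(J, 1e-6)
  scale_branch <- GI <= Jf
  ratio <- GI / Jf
  shift_scale <- (1 - GI) / pmax(1 - Jf, 1e-6)
  out <- array(0, d)
  for (ch in 1:3) {
    x <- stretched[, , ch]
    out[, , ch] <- ifelse(scale_branch, x * ratio,
                          shift_scale * (x - Jf) + GI)
  }
  rgb_image(clamp01(out))
}

#' Full hue-preserving enhancement pipeline
#'
#' Applies, in order: optional dominant-region selection (center crop,
#' resized back to the input geometry), global min-max stretch, CIECAM02
#' JCh decomposition, intensity extraction, global/local contrast
#' enhancement with fusion, and hue-preserving reconstruction. The
#' pipeline is deterministic: a fixed input and configuration always give
#' the same output.
#'
#' @param image an [rgb_image()] array.
#' @param config an [enhance_config()].
#' @param viewing CIECAM02 viewing conditions.
#' @return enhanced [rgb_image()] of the input geometry.
#' @export
enhance_image <- function(image, config = enhance_config(),
                          viewing = ciecam02_viewing()) {
  image <- rgb_image(image)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("enhance stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  if (config$roi_mode == "center_crop") {
    target <- dim(image)[1:2]
    image <- stage("roi", {
      crop <- center_crop(image, config$roi_fraction)
      out <- EBImage::resize(as_ebimage(crop), w = target[2], h = target[1],
                             filter = "bilinear")
      rgb_image(clamp01(from_ebimage(out)))
    })
  }
  stretched <- stage("global_stretch", global_stretch(image))
  jch <- stage("rgb_to_jch", rgb_to_jch(stretched, viewing))
  J <- stage("rgb_to_intensity", rgb_to_intensity(stretched))
  GI <- stage("enhance_intensity",
              enhance_intensity(J, jch$h_plane, config))
  stage("hue_preserving_reconstruct",
        hue_preserving_reconstruct(stretched, J, GI))
}
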