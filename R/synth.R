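#' The nine pigmented-skin-lesion classes
#'
#' Class labels in the fixed order used throughout the package: actinic
#' keratosis (AK), basal cell carcinoma (BCC), benign keratosis lesion
#' (BKL), dermatofibroma (DF), nevus (NV), melanoma (MEL), squamous cell
#' carcinoma (SCC), vascular lesion (VASC) and pigmented benign keratosis
#' (PBK).
#'
#' @return character vector of the 9 labels.
#' @export
psl_classes <- function() {
  c("AK", "BCC", "BKL", "DF", "NV", "MEL", "SCC", "VASC", "PBK")
}

#' Reference class composition of the pooled dermoscopy corpus
#'
#' Per-class image counts of the 24,000-image pooled collection the
#' pipeline emulates; [generate_manifest()] scales these counts.
#'
#' @return named integer vector over [psl_classes()].
#' @export
psl_class_counts <- function() {
  stats::setNames(c(700L, 3300L, 2600L, 200L, 12000L, 4000L, 600L, 300L,
                    300L), psl_classes())
}

#' Per-class parameters of the synthetic lesion generator
#'
#' Controls the class-conditional appearance of [synth_image()]: lesion
#' colour mean and spread, ellipse semi-axis range (as a fraction of the
#' image side), border irregularity amplitude, texture noise scale, and
#' hair-artifact probability. The default colour means are deliberately
#' separated by far more than two within-class standard deviations so the
#' nine classes are statistically separable by construction; they carry
#' no clinical meaning.
#'
#' @param label one of [psl_classes()].
#' @return list of generator parameters for the class.
#' @export
lesion_params <- function(label) {
  label <- match_psl_label(label)
  means <- list(
    AK   = c(0.72, 0.45, 0.35),
    BCC  = c(0.78, 0.55, 0.50),
    BKL  = c(0.45, 0.30, 0.18),
    DF   = c(0.55, 0.38, 0.30),
    NV   = c(0.40, 0.24, 0.12),
    MEL  = c(0.20, 0.12, 0.10),
    SCC  = c(0.80, 0.42, 0.38),
    VASC = c(0.60, 0.15, 0.25),
    PBK  = c(0.30, 0.20, 0.25))
  hair <- c(AK = 0.2, BCC = 0.2, BKL = 0.4, DF = 0.2, NV = 0.4,
            MEL = 0.4, SCC = 0.2, VASC = 0.1, PBK = 0.3)
  list(label = label,
       background_mean = c(0.86, 0.70, 0.60),
       background_sd = 0.02,
       lesion_mean = means[[label]],
       lesion_sd = 0.02,
       axes_range = c(0.15, 0.32),
       border_irregularity = 0.12,
       texture_sd = 0.03,
       hair_probability = unname(hair[label]))
}

match_psl_label <- function(label) {
  if (length(label) != 1L || !label %in% psl_classes())
    stop("unknown class label '", label, "'; valid labels: ",
         paste(psl_classes(), collapse = ", "))
  label
}

#' Generate a dataset manifest emulating the pooled corpus composition
#'
#' Builds a record table whose per-class counts are
#' `round(scale * reference_count)` (half up, minimum 1 per class so tiny
#' manifests keep all nine classes), deterministically shuffled by
#' `seed`. At `scale = 1` the manifest has 24,000 records.
#'
#' @param scale positive multiplier on the reference composition.
#' @param seed integer seed controlling shuffling and per-record image
#'   seeds.
#' @return a `dataset_manifest` data frame with columns `path`, `label`,
#'   `origin`, `source_path`, `image_seed`, `aug_seed`, `fold`.
#' @export
generate_manifest <- function(scale = 1, seed = 1L) {
  if (scale <= 0) stop("scale must be positive")
  counts <- stats::setNames(
    pmax(1L, as.integer(floor(psl_class_counts() * scale + 0.5))),
    psl_classes())
  rows <- lapply(psl_classes(), function(lab) {
    n <- counts[[lab]]
    data.frame(path = sprintf("img/%s_%05d.png", lab, seq_len(n)),
               label = lab, origin = "synthetic", source_path = NA_character_,
               image_seed = NA_integer_, aug_seed = NA_integer_,
               fold = NA_integer_, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest$image_seed <- derive_seed(seed, seq_len(nrow(manifest)))
  ord <- with_seed(seed, sample.int(nrow(manifest)))
  manifest <- manifest[ord, , drop = FALSE]
  rownames(manifest) <- NULL
  attr(manifest, "scale") <- scale
  attr(manifest, "seed") <- as.integer(seed)
  class(manifest) <- c("dataset_manifest", "data.frame")
  manifest
}

# smooth radial modulation for irregular lesion borders
border_profile <- function(theta, amp, phases, weights) {
  mod <- rep(1, length(theta))
  for (k in seq_along(phases))
    mod <- mod + amp * weights[k] * sin((k + 1) * theta + phases[k])
  mod
}

#' Render one synthetic dermoscopy-like image
#'
#' Draws a skin-toned background, one elliptical pigmented lesion with
#' class-conditional colour, irregular border and texture noise, and
#' (with the class's configured probability) dark hair strokes.
#' Deterministic per `(label, seed)`. The binary lesion mask is attached
#' as attribute `"lesion_mask"`.
#'
#' @param label one of [psl_classes()].
#' @param size image side length in pixels (at least 32).
#' @param seed integer seed.
#' @param params generator parameters, default [lesion_params()] for the
#'   class.
#' @return a `size x size x 3` [rgb_image()].
#' @export
synth_image <- function(label, size = 128L, seed = 1L,
                        params = lesion_params(label)) {
  label <- match_psl_label(label)
  size <- as.integer(size)
  if (size < 32L) stop("size must be at least 32 pixels")
  class_offset <- match(label, psl_classes()) * 1000003L
  with_seed(derive_seed(seed, class_offset), {
    bg <- clamp01(params$background_mean + rnorm(3, 0, params$background_sd))
    img <- array(rep(bg, each = size * size), c(size, size, 3))
    img <- img + array(rnorm(size * size, 0, 0.01), c(size, size, 3))

    # lesion geometry (axes as fractions of the side)
    axes <- sort(runif(2, params$axes_range[1], params$axes_range[2]))
    cx <- size * (0.5 + runif(1, -0.08, 0.08))
    cy <- size * (0.5 + runif(1, -0.08, 0.08))
    phi <- runif(1, 0, pi)
    phases <- runif(3, 0, 2 * pi)
    weights <- c(0.5, 0.3, 0.2)

    xs <- matrix(rep(seq_len(size), each = size), size, size)  # columns
    ys <- matrix(rep(seq_len(size), times = size), size, size) # rows
    dx <- xs - cx; dy <- ys - cy
    u <- (cos(phi) * dx + sin(phi) * dy) / (axes[1] * size)
    v <- (-sin(phi) * dx + cos(phi) * dy) / (axes[2] * size)
    rho <- sqrt(u^2 + v^2)
    theta <- atan2(v, u)
    edge <- border_profile(theta, params$border_irregularity, phases,
                           weights)
    soft <- clamp01((edge - rho) / (2 / size) * 0.5 + 0.5)  # ~2 px feather
    mask <- rho < edge

    col <- clamp01(params$lesion_mean + rnorm(3, 0, params$lesion_sd))
    texture <- matrix(rnorm(size * size, 0, params$texture_sd), size, size)
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - soft) +
        (col[ch] + texture) * soft

    if (runif(1) < params$hair_probability)
      img <- draw_hairs(img, n = sample(2:5, 1))

    img <- rgb_image(clamp01(img))
    attr(img, "lesion_mask") <- mask
    img
  })
}

# dark quadratic-bezier strokes emulating hair artifacts
draw_hairs <- function(img, n = 3L) {
  size <- dim(img)[1]
  for (i in seq_len(n)) {
    p <- matrix(runif(6, 1, size), 2, 3)
    t <- seq(0, 1, length.out = 4L * size)
    bx <- (1 - t)^2 * p[1, 1] + 2 * t * (1 - t) * p[1, 2] + t^2 * p[1, 3]
    by <- (1 - t)^2 * p[2, 1] + 2 * t * (1 - t) * p[2, 2] + t^2 * p[2, 3]
    rows <- pmin(size, pmax(1, round(by)))
    cols <- pmin(size, pmax(1, round(bx)))
    shade <- runif(1, 0.05, 0.2)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[cbind(rows, cols)] <- plane[cbind(rows, cols)] * 0.25 + shade * 0.75
      img[, , ch] <- plane
    }
  }
  img
}

#' Augmentation configuration
#'
#' The stochastic augmentation operators and their bounds: rotation angle
#' drawn in `[-rotation_max_deg, rotation_max_deg]`, brightness factor in
#' `brightness_range`, zoom and shear magnitudes, horizontal/vertical
#' flips, constant fill for exposed borders, additive Gaussian noise with
#' standard deviation `noise_sigma` on the rescaled `[0, 1]` intensity
#' scale (8-bit sources are rescaled by `rescale` = 1/255 on read), and
#' Gaussian blur applied with probability `blur_probability`.
#'
#' @param rotation_max_deg maximum absolute rotation, degrees.
#' @param brightness_range multiplicative brightness factor bounds.
#' @param zoom maximum relative zoom magnitude.
#' @param shear maximum shear magnitude.
#' @param fill_mode border fill; only `"constant"` is supported.
#' @param horizontal_flip,vertical_flip enable random flips.
#' @param rescale intensity rescale applied to 8-bit sources.
#' @param noise_sigma Gaussian noise standard deviation on `[0, 1]`.
#' @param blur_probability probability of Gaussian blur (sigma 1).
#' @return list of class `augment_config`.
#' @export
augment_config <- function(rotation_max_deg = 30, brightness_range = c(0.9, 1.1),
                           zoom = 0.1, shear = 0.1, fill_mode = "constant",
                           horizontal_flip = TRUE, vertical_flip = TRUE,
                           rescale = 1 / 255, noise_sigma = 0.45,
                           blur_probability = 0.25) {
  stopifnot(rotation_max_deg >= 0, zoom >= 0, shear >= 0, noise_sigma >= 0,
            blur_probability >= 0, blur_probability <= 1,
            identical(fill_mode, "constant"))
  structure(list(rotation_max_deg = rotation_max_deg,
                 brightness_range = brightness_range, zoom = zoom,
                 shear = shear, fill_mode = fill_mode,
                 horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip, rescale = rescale,
                 noise_sigma = noise_sigma,
                 blur_probability = blur_probability),
            class = "augment_config")
}

#' Apply a random augmentation draw to an image
#'
#' Draws rotation, zoom, shear, brightness, flips, noise and blur within
#' the configured bounds (deterministically for a given `seed`) and
#' applies them. Exposed borders are filled with the constant 0; output
#' values are clamped to `[0, 1]`. An all-zero configuration returns the
#' input unchanged.
#'
#' @param image an [rgb_image()] array.
#' @param config an [augment_config()].
#' @param seed integer seed for the random draw.
#' @return augmented [rgb_image()] of the same geometry.
#' @export
augment <- function(image, config = augment_config(), seed = 1L) {
  image <- rgb_image(image)
  with_seed(derive_seed(seed, 97L), {
    h <- dim(image)[1]; w <- dim(image)[2]
    angle <- if (config$rotation_max_deg > 0)
      runif(1, -config$rotation_max_deg, config$rotation_max_deg) else 0
    zoomf <- if (config$zoom > 0)
      1 + runif(1, -config$zoom, config$zoom) else 1
    shearf <- if (config$shear > 0)
      runif(1, -config$shear, config$shear) else 0
    bright <- runif(1, config$brightness_range[1], config$brightness_range[2])
    do_h <- config$horizontal_flip && runif(1) < 0.5
    do_v <- config$vertical_flip && runif(1) < 0.5
    do_blur <- config$blur_probability > 0 && runif(1) < config$blur_probability

    if (do_h) image <- image[, w:1, , drop = FALSE]
    if (do_v) image <- image[h:1, , , drop = FALSE]

    if (abs(angle) > 1e-12 || abs(zoomf - 1) > 1e-12 ||
        abs(shearf) > 1e-12) {
      a <- angle * pi / 180
      rot <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
      shear_m <- matrix(c(1, shearf, 0, 1), 2, 2)
      A <- rot %*% shear_m * zoomf
      ctr <- c(w, h) / 2
      b <- ctr - as.vector(A %*% ctr)
      m <- rbind(t(A), b)  # EBImage: px_new = cbind(px, 1) %*% m
      image <- clamp01(from_ebimage(
        EBImage::affine(as_ebimage(image), m, filter = "bilinear",
                        output.dim = c(w, h), bg.col = 0)))
    }

    image <- image * bright
    if (config$noise_sigma > 0)
      image <- image + array(rnorm(length(image), 0, config$noise_sigma),
                             dim(image))
    if (do_blur)
      image <- from_ebimage(EBImage::gblur(as_ebimage(clamp01(image)),
                                           sigma = 1))
    rgb_image(clamp01(image))
  })
}

#' Balance a manifest by class-conditional augmentation records
#'
#' Adds `origin = "augmented"` records, each referencing a source record
#' of the same class and a fixed augmentation seed, until every class
#' count equals the largest original class count. No original record is
#' removed; an already balanced manifest is returned unchanged.
#'
#' @param manifest a `dataset_manifest`.
#' @param config an [augment_config()] (recorded for materialization).
#' @return balanced `dataset_manifest`.
#' @export
balance_classes <- function(manifest, config = augment_config()) {
  stopifnot(nrow(manifest) > 0)
  for (col in c("source_path", "image_seed", "aug_seed", "fold"))
    if (is.null(manifest[[col]]))
      manifest[[col]] <- if (col == "source_path") NA_character_ else NA_integer_
  counts <- table(factor(manifest$label, levels = psl_classes()))
  counts <- counts[counts > 0]
  target <- max(counts)
  seed0 <- attr(manifest, "seed")
  if (is.null(seed0)) seed0 <- 0L
  extra <- list()
  for (lab in names(counts)) {
    deficit <- target - counts[[lab]]
    if (deficit == 0) next
    src <- manifest[manifest$label == lab, , drop = FALSE]
    pick <- with_seed(derive_seed(seed0, match(lab, psl_classes())),
                      sample.int(nrow(src), deficit, replace = TRUE))
    add <- src[pick, , drop = FALSE]
    add$origin <- "augmented"
    add$source_path <- add$path
    add$aug_seed <- derive_seed(seed0,
                                match(lab, psl_classes()) * 100003L +
                                  seq_len(deficit))
    add$path <- sprintf("aug/%s_a%05d.png", lab, seq_len(deficit))
    extra[[lab]] <- add
  }
  if (!length(extra)) return(manifest)
  out <- rbind(manifest, do.call(rbind, extra))
  rownames(out) <- NULL
  attr(out, "scale") <- attr(manifest, "scale")
  attr(out, "seed") <- seed0
  attr(out, "augment_config") <- config
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Materialize manifest records as images
#'
#' Produces the pixel data for one manifest record: reads the file if
#' `record$path` exists under `dir`, otherwise renders it with
#' [synth_image()] (and, for augmented records, [augment()]); the result
#' is resized to `size`.
#'
#' @param record one manifest row.
#' @param size side length in pixels.
#' @param dir optional directory against which paths are resolved.
#' @param config augmentation configuration for augmented records.
#' @return an [rgb_image()] array.
#' @export
load_record_image <- function(record, size = 128L, dir = NULL,
                              config = augment_config()) {
  path <- if (!is.null(dir)) file.path(dir, record$path) else record$path
  if (!is.na(path) && file.exists(path)) {
    img <- read_image(path)
  } else {
    img <- synth_image(record$label, size = size, seed = record$image_seed)
    if (identical(record$origin, "augmented"))
      img <- augment(img, config, seed = record$aug_seed)
  }
  resize_image(rgb_image(clamp01(unclass(img))), size)
}

#' @describeIn load_record_image write every record of a manifest as a
#'   PNG under `dir` and return the manifest with resolved paths.
#' @param manifest a `dataset_manifest`.
#' @export
materialize_manifest <- function(manifest, dir, size = 128L,
                                 config = augment_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, , drop = FALSE]
    out <- file.path(dir, rec$path)
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    write_image(load_record_image(rec, size = size, config = config), out)
  }
  manifest$path <- file.path(dir, manifest$path)
  manifest
}
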