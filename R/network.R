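#' Spark module configuration
#'
#' A spark module is the depthwise-separable variant of the SqueezeNet
#' fire module: a 1x1 squeeze convolution with `squeeze_channels` filters
#' feeding two parallel expand paths — a 1x1 convolution with
#' `expand1x1_channels` filters and a depthwise-separable 3x3 convolution
#' with `expand3x3_channels` filters — whose outputs are concatenated.
#' Every convolution is paired with batch normalization and a GELU (or
#' ReLU) activation. The squeeze layer is a bottleneck:
#' `squeeze_channels <= expand1x1_channels + expand3x3_channels`.
#'
#' @param in_channels,squeeze_channels,expand1x1_channels,expand3x3_channels
#'   positive channel counts.
#' @param use_batchnorm attach batch normalization to each convolution.
#' @param activation `"gelu"` or `"relu"`.
#' @return list of class `spark_config`; output channel count is
#'   `expand1x1_channels + expand3x3_channels`.
#' @export
spark_config <- function(in_channels, squeeze_channels, expand1x1_channels,
                         expand3x3_channels, use_batchnorm = TRUE,
                         activation = c("gelu", "relu")) {
  activation <- match.arg(activation)
  stopifnot(in_channels >= 1, squeeze_channels >= 1,
            expand1x1_channels >= 1, expand3x3_channels >= 1)
  if (squeeze_channels > expand1x1_channels + expand3x3_channels)
    stop("squeeze_channels must not exceed the total expand channels")
  structure(list(in_channels = as.integer(in_channels),
                 squeeze_channels = as.integer(squeeze_channels),
                 expand1x1_channels = as.integer(expand1x1_channels),
                 expand3x3_channels = as.integer(expand3x3_channels),
                 out_channels = as.integer(expand1x1_channels +
                                             expand3x3_channels),
                 use_batchnorm = isTRUE(use_batchnorm),
                 activation = activation),
            class = "spark_config")
}

#' Network configuration
#'
#' The compact SqueezeNet-style classification network: a strided 3x3
#' stem convolution, eight spark modules with three interleaved max-pool
#' stages (after the stem and after the second and fourth spark modules)
#' plus one global pooling stage, dropout, a 1x1 convolution onto the
#' class logits, global average pooling and softmax. The default channel
#' plan is the frozen result of [calibrate_network_plan()] with its
#' default parameter budget of 3,182,412 trainable parameters at the
#' 512 x 512 x 3 input geometry.
#'
#' `width_multiplier` scales every channel count, rounding to the nearest
#' multiple of 8 with a floor of 8 (the frozen plan itself is kept exact
#' at multiplier 1).
#'
#' @param input_size square input side in pixels.
#' @param num_classes number of output classes.
#' @param stem_channels stem convolution output channels.
#' @param sparks list of 8 integer triples `(S, E1, E3)`.
#' @param pool_after indices after which a 2x2 max-pool follows (0 means
#'   after the stem); exactly three pool stages are required.
#' @param dropout_rate dropout probability before the head, in
#'   `[0.2, 0.6]`.
#' @param width_multiplier positive channel-width scale.
#' @param use_batchnorm,activation forwarded to every [spark_config()].
#' @return list of class `network_config`.
#' @export
network_config <- function(input_size = 512L, num_classes = 9L,
                           stem_channels = 252L,
                           sparks = list(c(64L, 240L, 240L),
                                         c(64L, 240L, 240L),
                                         c(120L, 480L, 480L),
                                         c(120L, 480L, 480L),
                                         c(184L, 720L, 720L),
                                         c(184L, 720L, 720L),
                                         c(240L, 960L, 960L),
                                         c(218L, 945L, 960L)),
                           pool_after = c(0L, 2L, 4L),
                           dropout_rate = 0.5, width_multiplier = 1,
                           use_batchnorm = TRUE,
                           activation = c("gelu", "relu")) {
  activation <- match.arg(activation)
  if (length(pool_after) != 3L)
    stop("exactly three max-pool stages are required")
  if (dropout_rate < 0.2 || dropout_rate > 0.6)
    stop("dropout_rate must lie in [0.2, 0.6]")
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  scale8 <- function(x) {
    if (width_multiplier == 1) return(as.integer(x))
    pmax(8L, as.integer(floor(x * width_multiplier / 8 + 0.5) * 8L))
  }
  stem_channels <- scale8(stem_channels)
  sparks <- lapply(sparks, scale8)
  cfg <- list(input_size = as.integer(input_size), input_channels = 3L,
              num_classes = as.integer(num_classes),
              stem_channels = stem_channels, sparks = sparks,
              pool_after = as.integer(pool_after),
              dropout_rate = dropout_rate,
              width_multiplier = width_multiplier,
              use_batchnorm = isTRUE(use_batchnorm),
              activation = activation)
  class(cfg) <- "network_config"
  cfg
}

#' Parameter count of a single convolutional layer
#'
#' Closed-form trainable-parameter counts: a standard `N x N` convolution
#' holds `C2 * C1 * N^2` weights; its depthwise-separable factorization
#' holds `C1 * N^2` (depthwise) plus `C1 * C2` (pointwise). Optional
#' biases add `C2` (standard/pointwise/depthwise outputs) or `C1 + C2`
#' (separable); attached batch normalization adds 2 per normalized
#' channel (`2*C2`, or `2*C1 + 2*C2` for the separable pair).
#'
#' @param kind `"standard"`, `"depthwise"`, `"pointwise"` or
#'   `"separable"`.
#' @param in_channels,out_channels channel counts C1, C2.
#' @param kernel kernel side N (forced to 1 for pointwise).
#' @param bias include bias terms.
#' @param batchnorm include attached batch-normalization parameters.
#' @return integer parameter count.
#' @export
conv_param_count <- function(kind = c("standard", "depthwise", "pointwise",
                                      "separable"),
                             in_channels, out_channels = in_channels,
                             kernel = 3L, bias = FALSE, batchnorm = FALSE) {
  kind <- match.arg(kind)
  C1 <- as.numeric(in_channels); C2 <- as.numeric(out_channels)
  N <- if (kind == "pointwise") 1 else as.numeric(kernel)
  n <- switch(kind,
              standard = C2 * C1 * N^2 + if (bias) C2 else 0,
              pointwise = C2 * C1 + if (bias) C2 else 0,
              depthwise = C1 * N^2 + if (bias) C1 else 0,
              separable = C1 * N^2 + C1 * C2 +
                if (bias) C1 + C2 else 0)
  if (batchnorm)
    n <- n + switch(kind, separable = 2 * (C1 + C2), depthwise = 2 * C1,
                    2 * C2)
  as.integer(n)
}

# ---- building --------------------------------------------------------

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

new_conv_layer <- function(name, C1, C2, k = 1L, stride = 1L, pad = 0L,
                           bias = FALSE, bn = TRUE, act = "gelu") {
  layer <- list(type = "conv", name = name,
                C1 = C1, C2 = C2, k = k, stride = stride, pad = pad,
                has_bias = bias, has_bn = bn, act = act,
                w = he_init(c(C1, k, k, C2), C1 * k * k),
                b = if (bias) numeric(C2) else NULL,
                gamma = if (bn) rep(1, C2) else NULL,
                beta = if (bn) numeric(C2) else NULL,
                run_mean = if (bn) numeric(C2) else NULL,
                run_var = if (bn) rep(1, C2) else NULL,
                env = new.env(parent = emptyenv()))
  layer
}

new_depthwise_layer <- function(name, C, k = 3L, bn = TRUE, act = "gelu") {
  list(type = "depthwise", name = name, C = C, k = k,
       has_bn = bn, act = act,
       w = he_init(c(C, k, k), k * k),
       gamma = if (bn) rep(1, C) else NULL,
       beta = if (bn) numeric(C) else NULL,
       run_mean = if (bn) numeric(C) else NULL,
       run_var = if (bn) rep(1, C) else NULL,
       env = new.env(parent = emptyenv()))
}

#' Build a spark module
#'
#' Instantiates the module graph of a [spark_config()]: squeeze 1x1
#' (BN + activation), then in parallel an expand 1x1 path and a
#' depthwise-separable 3x3 path (each BN + activation), concatenated
#' along channels.
#'
#' @param config a [spark_config()].
#' @param name layer-name prefix.
#' @return spark layer object usable inside a network.
#' @export
build_spark <- function(config, name = "spark") {
  stopifnot(inherits(config, "spark_config"))
  bn <- config$use_batchnorm; act <- config$activation
  list(type = "spark", name = name, config = config,
       sq = new_conv_layer(paste0(name, ".sq"), config$in_channels,
                           config$squeeze_channels, bn = bn, act = act),
       e1 = new_conv_layer(paste0(name, ".e1"), config$squeeze_channels,
                           config$expand1x1_channels, bn = bn, act = act),
       dw = new_depthwise_layer(paste0(name, ".dw"),
                                config$squeeze_channels, bn = bn,
                                act = act),
       pw = new_conv_layer(paste0(name, ".pw"), config$squeeze_channels,
                           config$expand3x3_channels, bn = bn, act = act))
}

#' Build the classification network
#'
#' Materializes the layer graph of a [network_config()] with
#' He-initialized weights (deterministic given `seed`).
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return list of class `dermlight_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  with_seed(derive_seed(seed, 11L), {
    bn <- config$use_batchnorm; act <- config$activation
    layers <- list()
    layers[["stem"]] <- new_conv_layer("stem", config$input_channels,
                                       config$stem_channels, k = 3L,
                                       stride = 2L, pad = 1L,
                                       bias = !bn, bn = bn, act = act)
    if (0L %in% config$pool_after)
      layers[["pool0"]] <- list(type = "maxpool", name = "pool0")
    cin <- config$stem_channels
    for (i in seq_along(config$sparks)) {
      s <- config$sparks[[i]]
      sc <- spark_config(cin, s[1], s[2], s[3], use_batchnorm = bn,
                         activation = act)
      nm <- paste0("spark", i)
      layers[[nm]] <- build_spark(sc, nm)
      cin <- sc$out_channels
      if (i %in% config$pool_after)
        layers[[paste0("pool", i)]] <- list(type = "maxpool",
                                            name = paste0("pool", i))
    }
    layers[["dropout"]] <- list(type = "dropout", name = "dropout",
                                rate = config$dropout_rate)
    layers[["head"]] <- new_conv_layer("head", cin, config$num_classes,
                                       k = 1L, bias = TRUE, bn = FALSE,
                                       act = "none")
    layers[["gap"]] <- list(type = "gap", name = "gap")
    structure(list(config = config, layers = layers),
              class = "dermlight_network")
  })
}

# ---- forward / backward ----------------------------------------------

act_forward <- function(x, act) {
  switch(act, gelu = gelu_forward(x), relu = pmax(x, 0), none = x)
}

act_backward <- function(dout, x, act) {
  switch(act, gelu = gelu_backward(dout, x),
         relu = dout * (x > 0), none = dout)
}

conv_unit_forward <- function(layer, x, training) {
  key <- paste(dim(x)[1:3], collapse = "x")
  im <- layer$env[[key]]
  cf <- conv_forward(x, layer$w, layer$b, layer$stride, layer$pad, im)
  if (is.null(im)) layer$env[[key]] <- cf$im
  pre <- cf$out
  cache <- list(col = cf$col, im = cf$im)
  if (layer$has_bn) {
    bnf <- bn_forward(pre, layer$gamma, layer$beta, layer$run_mean,
                      layer$run_var, training)
    layer$run_mean <- bnf$run_mean; layer$run_var <- bnf$run_var
    cache$bn <- list(xhat = bnf$xhat, inv = bnf$inv)
    pre_act <- bnf$out
  } else pre_act <- pre
  cache$pre_act <- pre_act
  list(out = act_forward(pre_act, layer$act), cache = cache,
       layer = layer)
}

conv_unit_backward <- function(layer, cache, dout) {
  d <- act_backward(dout, cache$pre_act, layer$act)
  grads <- list()
  if (layer$has_bn) {
    bb <- bn_backward(d, cache$bn, layer$gamma)
    grads$gamma <- bb$dgamma; grads$beta <- bb$dbeta
    d <- bb$dx
  }
  cb <- conv_backward(d, cache, layer$w, layer$has_bias)
  grads$w <- cb$dw
  if (layer$has_bias) grads$b <- cb$db
  list(dx = cb$dx, grads = grads)
}

dw_unit_forward <- function(layer, x, training) {
  key <- paste(dim(x)[1:3], collapse = "x")
  im <- layer$env[[key]]
  df <- depthwise_forward(x, layer$w, im)
  if (is.null(im)) layer$env[[key]] <- df$im
  cache <- list(col = df$col, im = df$im)
  if (layer$has_bn) {
    bnf <- bn_forward(df$out, layer$gamma, layer$beta, layer$run_mean,
                      layer$run_var, training)
    layer$run_mean <- bnf$run_mean; layer$run_var <- bnf$run_var
    cache$bn <- list(xhat = bnf$xhat, inv = bnf$inv)
    pre_act <- bnf$out
  } else pre_act <- df$out
  cache$pre_act <- pre_act
  list(out = act_forward(pre_act, layer$act), cache = cache,
       layer = layer)
}

dw_unit_backward <- function(layer, cache, dout) {
  d <- act_backward(dout, cache$pre_act, layer$act)
  grads <- list()
  if (layer$has_bn) {
    bb <- bn_backward(d, cache$bn, layer$gamma)
    grads$gamma <- bb$dgamma; grads$beta <- bb$dbeta
    d <- bb$dx
  }
  db <- depthwise_backward(d, cache, layer$w)
  grads$w <- db$dw
  list(dx = db$dx, grads = grads)
}

spark_forward <- function(layer, x, training) {
  sq <- conv_unit_forward(layer$sq, x, training); layer$sq <- sq$layer
  e1 <- conv_unit_forward(layer$e1, sq$out, training); layer$e1 <- e1$layer
  dw <- dw_unit_forward(layer$dw, sq$out, training); layer$dw <- dw$layer
  pw <- conv_unit_forward(layer$pw, dw$out, training); layer$pw <- pw$layer
  d1 <- dim(e1$out); d3 <- dim(pw$out)
  out <- array(0, c(d1[1] + d3[1], d1[2], d1[3], d1[4]))
  out[seq_len(d1[1]), , , ] <- e1$out
  out[d1[1] + seq_len(d3[1]), , , ] <- pw$out
  list(out = out,
       cache = list(sq = sq$cache, e1 = e1$cache, dw = dw$cache,
                    pw = pw$cache, e1_channels = d1[1]),
       layer = layer)
}

spark_backward <- function(layer, cache, dout) {
  ne1 <- cache$e1_channels
  d_e1 <- dout[seq_len(ne1), , , , drop = FALSE]
  d_pw <- dout[(ne1 + 1):dim(dout)[1], , , , drop = FALSE]
  b_e1 <- conv_unit_backward(layer$e1, cache$e1, d_e1)
  b_pw <- conv_unit_backward(layer$pw, cache$pw, d_pw)
  b_dw <- dw_unit_backward(layer$dw, cache$dw, b_pw$dx)
  d_sq <- b_e1$dx + b_dw$dx
  b_sq <- conv_unit_backward(layer$sq, cache$sq, d_sq)
  grads <- list(sq = b_sq$grads, e1 = b_e1$grads, dw = b_dw$grads,
                pw = b_pw$grads)
  list(dx = b_sq$dx, grads = grads)
}

# Full forward pass. Returns logits (num_classes x N); with
# `with_caches = TRUE` also the per-layer caches needed for backprop and
# the (possibly updated) network.
network_forward <- function(net, x, training = FALSE, with_caches = FALSE,
                            taps = NULL) {
  caches <- list(); tap_out <- list()
  for (nm in names(net$layers)) {
    layer <- net$layers[[nm]]
    res <- switch(layer$type,
      conv = conv_unit_forward(layer, x, training),
      depthwise = dw_unit_forward(layer, x, training),
      spark = spark_forward(layer, x, training),
      maxpool = { mp <- maxpool_forward(x); list(out = mp$out, cache = mp,
                                                 layer = layer) },
      dropout = { dp <- dropout_forward(x, layer$rate, training)
                  list(out = dp$out, cache = dp, layer = layer) },
      gap = { gp <- gap_forward(x); list(out = gp$out, cache = gp,
                                         layer = layer) },
      stop("unknown layer type: ", layer$type))
    net$layers[[nm]] <- res$layer
    x <- res$out
    if (with_caches) caches[[nm]] <- res$cache
    if (!is.null(taps) && nm %in% taps) tap_out[[nm]] <- res$out
  }
  list(logits = x, caches = caches, net = net, taps = tap_out)
}

network_backward <- function(net, caches, dlogits) {
  grads <- list()
  d <- dlogits
  for (nm in rev(names(net$layers))) {
    layer <- net$layers[[nm]]
    res <- switch(layer$type,
      conv = conv_unit_backward(layer, caches[[nm]], d),
      depthwise = dw_unit_backward(layer, caches[[nm]], d),
      spark = spark_backward(layer, caches[[nm]], d),
      maxpool = list(dx = maxpool_backward(d, caches[[nm]])),
      dropout = list(dx = dropout_backward(d, caches[[nm]])),
      gap = list(dx = gap_backward(d, caches[[nm]])))
    d <- res$dx
    if (!is.null(res$grads)) grads[[nm]] <- res$grads
  }
  grads
}

#' Run the network on a batch of images
#'
#' Converts a batch of RGB images to the internal channel-first tensor,
#' runs the forward pass in inference mode and returns softmax class
#' probabilities (and optionally intermediate activations at named
#' layers, e.g. `"spark8"`).
#'
#' @param net a [build_network()] network.
#' @param images list of [rgb_image()] arrays, or a `(3, H, W, N)`
#'   tensor.
#' @param tap_points optional character vector of layer names whose
#'   activations are returned.
#' @return list with `probabilities` (`N x num_classes` matrix) and
#'   `taps` (named list of activation tensors).
#' @export
net_forward <- function(net, images, tap_points = NULL) {
  x <- if (is.list(images)) images_to_tensor(images) else images
  sz <- net$config$input_size
  if (dim(x)[2] != sz || dim(x)[3] != sz)
    stop("input geometry ", dim(x)[2], "x", dim(x)[3],
         " does not match the configured ", sz, "x", sz)
  fw <- network_forward(net, x, training = FALSE, taps = tap_points)
  probs <- t(softmax_cols(fw$logits))
  colnames(probs) <- paste0("class", seq_len(ncol(probs)))
  list(probabilities = probs, taps = fw$taps)
}

#' Apply a depthwise-separable convolution to a feature map
#'
#' The factorized convolution: per-channel 3x3 (or `k x k`) spatial
#' filtering followed by a 1x1 pointwise projection onto the output
#' channel space.
#'
#' @param x tensor `(C1, H, W, N)` (a 3D `(C1, H, W)` input is promoted
#'   to batch size 1).
#' @param depthwise_w array `(C1, k, k)`.
#' @param pointwise_w matrix `(C1, C2)` or array `(C1, 1, 1, C2)`.
#' @return tensor `(C2, H, W, N)` (same spatial size; same padding).
#' @export
apply_sepconv <- function(x, depthwise_w, pointwise_w) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  dwf <- depthwise_forward(x, depthwise_w)
  if (is.matrix(pointwise_w))
    dim(pointwise_w) <- c(nrow(pointwise_w), 1L, 1L, ncol(pointwise_w))
  conv_forward(dwf$out, pointwise_w)$out
}

# list of H x W x 3 images -> (3, H, W, N) tensor
images_to_tensor <- function(images) {
  d <- dim(images[[1]])
  x <- array(0, c(3L, d[1], d[2], length(images)))
  for (i in seq_along(images)) x[, , , i] <- aperm(images[[i]], c(3, 1, 2))
  x
}

# ---- accounting ------------------------------------------------------

# Per-layer ledger rows for a configuration (no tensors needed).
plan_ledger <- function(config) {
  rows <- list()
  add <- function(name, kind, params, macs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, kind = kind, param_count = as.integer(params),
      flop_count = 2 * as.numeric(macs), stringsAsFactors = FALSE)
  }
  bn2 <- function(c) if (config$use_batchnorm) 2 * c else 0
  sz <- config$input_size
  s <- floor(sz / 2)  # stem stride 2, same padding
  stem_p <- config$stem_channels * config$input_channels * 9 +
    (if (config$use_batchnorm) 2 * config$stem_channels
     else config$stem_channels)  # bias when no BN
  add("stem", "standard", stem_p,
      s * s * config$stem_channels * config$input_channels * 9)
  if (0L %in% config$pool_after) s <- floor(s / 2)
  cin <- config$stem_channels
  for (i in seq_along(config$sparks)) {
    sp <- config$sparks[[i]]
    S <- sp[1]; E1 <- sp[2]; E3 <- sp[3]
    nm <- paste0("spark", i)
    add(paste0(nm, ".sq"), "pointwise", S * cin + bn2(S), s * s * S * cin)
    add(paste0(nm, ".e1"), "pointwise", E1 * S + bn2(E1), s * s * E1 * S)
    add(paste0(nm, ".dw"), "depthwise", S * 9 + bn2(S), s * s * S * 9)
    add(paste0(nm, ".pw"), "pointwise", E3 * S + bn2(E3), s * s * E3 * S)
    cin <- E1 + E3
    if (i %in% config$pool_after) s <- floor(s / 2)
  }
  add("head", "pointwise", config$num_classes * cin + config$num_classes,
      s * s * config$num_classes * cin)
  do.call(rbind, rows)
}

#' Parameter ledger of a network
#'
#' Per-layer trainable-parameter and FLOP accounting. The FLOP convention
#' counts 1 multiply-accumulate as 2 FLOPs and excludes batch
#' normalization, activations and pooling; the serialized-size estimate
#' assumes 4 bytes per parameter. The ledger total is cross-checked
#' against the number of elements actually held in the network's weight
#' arrays (the backend count) and the two must agree exactly.
#'
#' @param net a [build_network()] network (or a [network_config()], in
#'   which case no backend cross-check is possible).
#' @return a `param_report`: data frame of per-layer rows with attributes
#'   `total_params`, `backend_params`, `mflops`, `size_mb`.
#' @export
count_parameters <- function(net) {
  config <- if (inherits(net, "network_config")) net else net$config
  ledger <- plan_ledger(config)
  total <- as.integer(sum(ledger$param_count))
  backend <- if (inherits(net, "dermlight_network"))
    as.integer(sum(vapply(collect_params(net), length, integer(1))))
  else NA_integer_
  structure(ledger, class = c("param_report", "data.frame"),
            total_params = total, backend_params = backend,
            mflops = sum(ledger$flop_count) / 1e6,
            size_mb = total * 4 / 2^20,
            flop_convention = "1 MAC = 2 FLOPs; BN/activation/pooling excluded")
}

#' @describeIn count_parameters total forward FLOPs (in MFLOPs) at a
#'   given square input size.
#' @param input_size input side length in pixels (defaults to the
#'   configured size).
#' @export
count_flops <- function(net, input_size = NULL) {
  config <- if (inherits(net, "network_config")) net else net$config
  if (!is.null(input_size)) config$input_size <- as.integer(input_size)
  sum(plan_ledger(config)$flop_count) / 1e6
}

# named flat list of every trainable array in the network
collect_params <- function(net) {
  out <- list()
  grab <- function(layer) {
    p <- list()
    if (!is.null(layer[["w"]])) p$w <- layer[["w"]]
    if (!is.null(layer[["b"]])) p$b <- layer[["b"]]
    if (!is.null(layer[["gamma"]])) {
      p$gamma <- layer[["gamma"]]; p$beta <- layer[["beta"]]
    }
    p
  }
  for (layer in net$layers) {
    if (layer$type == "spark") {
      for (part in c("sq", "e1", "dw", "pw")) {
        p <- grab(layer[[part]])
        names(p) <- paste(layer$name, part, names(p), sep = ".")
        out <- c(out, p)
      }
    } else if (layer$type %in% c("conv", "depthwise")) {
      p <- grab(layer)
      names(p) <- paste(layer$name, names(p), sep = ".")
      out <- c(out, p)
    }
  }
  out
}

assign_params <- function(net, params) {
  put <- function(layer, prefix) {
    for (f in c("w", "b", "gamma", "beta")) {
      key <- paste(prefix, f, sep = ".")
      if (!is.null(params[[key]])) layer[[f]] <- params[[key]]
    }
    layer
  }
  for (nm in names(net$layers)) {
    layer <- net$layers[[nm]]
    if (layer$type == "spark") {
      for (part in c("sq", "e1", "dw", "pw"))
        layer[[part]] <- put(layer[[part]], paste(layer$name, part,
                                                  sep = "."))
      net$layers[[nm]] <- layer
    } else if (layer$type %in% c("conv", "depthwise")) {
      net$layers[[nm]] <- put(layer, layer$name)
    }
  }
  net
}

# flatten nested gradient lists into the collect_params naming
flatten_grads <- function(grads) {
  out <- list()
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (all(names(g) %in% c("sq", "e1", "dw", "pw"))) {
      for (part in names(g))
        for (f in names(g[[part]]))
          out[[paste(nm, part, f, sep = ".")]] <- g[[part]][[f]]
    } else {
      for (f in names(g)) out[[paste(nm, f, sep = ".")]] <- g[[f]]
    }
  }
  out
}

# ---- width calibration ----------------------------------------------

#' Calibrate the channel plan to a parameter budget
#'
#' Fixes the network's channel plan so that the total trainable-parameter
#' count matches `target_params` exactly. The search proceeds in two
#' stages over the classical SqueezeNet v1.1 skeleton with
#' depthwise-separable expand paths: (1) a coarse grid over the width
#' multiplier (multiples of 0.125, channels rounded to multiples of 8)
#' picks the closest plan; (2) an exact integer refinement jointly
#' adjusts the stem width and the last spark module's squeeze width by
#' single channels, solving for the last module's 1x1 expand width in
#' closed form (the total is linear in that width with slope
#' `S8 + 2 + num_classes`). Among exact solutions the smallest total
#' adjustment is taken, so the result is deterministic.
#'
#' @param target_params parameter budget (total trainable parameters).
#' @param input_size,num_classes geometry of the calibrated
#'   configuration.
#' @return a [network_config()] whose [count_parameters()] total equals
#'   `target_params`.
#' @export
calibrate_network_plan <- function(target_params = 3182412L,
                                   input_size = 512L, num_classes = 9L) {
  base_stem <- 64
  base_sparks <- list(c(16, 64, 64), c(16, 64, 64), c(32, 128, 128),
                      c(32, 128, 128), c(48, 192, 192), c(48, 192, 192),
                      c(64, 256, 256), c(64, 256, 256))
  r8 <- function(x) pmax(8L, as.integer(floor(x / 8 + 0.5) * 8L))
  count_plan <- function(stem, sparks) {
    total <- 29 * stem
    cin <- stem
    for (s in sparks) {
      total <- total + s[1] * (cin + s[2] + s[3] + 13) + 2 * (s[2] + s[3])
      cin <- s[2] + s[3]
    }
    total + num_classes * cin + num_classes
  }
  # stage 1: coarse width grid
  ws <- seq(0.25, 8, by = 0.125)
  counts <- vapply(ws, function(w)
    count_plan(r8(base_stem * w), lapply(base_sparks, function(s) r8(s * w))),
    numeric(1))
  w0 <- ws[which.min(abs(counts - target_params))]
  stem0 <- r8(base_stem * w0)
  sparks0 <- lapply(base_sparks, function(s) r8(s * w0))
  # stage 2: exact integer refinement on (stem, S8), solving E1_8
  S8_0 <- sparks0[[8]][1]; E1_0 <- sparks0[[8]][2]; E3_8 <- sparks0[[8]][3]
  slope0 <- NULL; best <- NULL
  for (dstem in -64:64) {
    for (dS8 in -64:64) {
      sp <- sparks0
      sp[[8]][1] <- S8_0 + dS8
      sp[[8]][2] <- 0L
      a <- count_plan(stem0 + dstem, sp)
      slope <- (S8_0 + dS8) + 2 + num_classes
      rem <- target_params - a
      if (rem %% slope != 0) next
      e1 <- rem %/% slope
      if (e1 < 8 || (S8_0 + dS8) > e1 + E3_8 || e1 > 4 * E3_8) next
      cost <- abs(dstem) + abs(dS8) + abs(e1 - E1_0)
      if (is.null(best) || cost < best$cost ||
          (cost == best$cost && (dstem < best$dstem ||
                                 (dstem == best$dstem && dS8 < best$dS8))))
        best <- list(dstem = dstem, dS8 = dS8, e1 = e1, cost = cost)
    }
  }
  if (is.null(best))
    stop("no exact channel plan found for target ", target_params)
  sparks0[[8]][1] <- S8_0 + best$dS8
  sparks0[[8]][2] <- best$e1
  network_config(input_size = input_size, num_classes = num_classes,
                 stem_channels = stem0 + best$dstem,
                 sparks = lapply(sparks0, as.integer))
}
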