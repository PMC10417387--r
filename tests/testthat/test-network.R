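test_that("convolution parameter formulas evaluate exactly", {
  expect_equal(conv_param_count("standard", 64, 128, 3), 73728L)
  expect_equal(conv_param_count("separable", 64, 128, 3), 8768L)
  expect_equal(conv_param_count("standard", 3, 8, 3, bias = TRUE), 224L)
  # 1x1 separable degenerates to per-channel scale + pointwise
  expect_equal(conv_param_count("separable", 16, 32, 1), 16L + 16L * 32L)
  expect_equal(conv_param_count("pointwise", 16, 32), 512L)
  expect_equal(conv_param_count("depthwise", 16, kernel = 3), 144L)
  # batchnorm attachment
  expect_equal(conv_param_count("standard", 4, 8, 3, batchnorm = TRUE),
               4L * 8L * 9L + 16L)
})

test_that("separable factorization always beats the standard count", {
  for (n in 2:5)
    for (c1 in c(1, 3, 16, 64))
      for (c2 in c(2, 8, 128))
        expect_lt(conv_param_count("separable", c1, c2, n),
                  conv_param_count("standard", c1, c2, n))
})

test_that("sepconv with delta depthwise and identity pointwise is identity", {
  set.seed(10)
  C <- 4
  x <- array(runif(C * 8 * 8), c(C, 8, 8, 2))
  dw <- array(0, c(C, 3, 3)); dw[, 2, 2] <- 1
  pw <- diag(C)
  out <- apply_sepconv(x, dw, pw)
  expect_lt(max(abs(out - x)), 1e-12)
})

test_that("constant input through an all-ones depthwise kernel sums the patch", {
  v <- 0.37
  x <- array(v, c(1, 6, 6, 1))
  dw <- array(1, c(1, 3, 3))
  out <- apply_sepconv(x, dw, matrix(1, 1, 1))
  expect_equal(out[1, 3, 3, 1], 9 * v, tolerance = 1e-12)  # interior
  expect_equal(out[1, 1, 1, 1], 4 * v, tolerance = 1e-12)  # corner
})

test_that("rank-1 sepconv matches the equivalent standard convolution", {
  set.seed(11)
  C1 <- 3; C2 <- 5; k <- 3
  x <- array(runif(C1 * 8 * 8), c(C1, 8, 8, 1))
  theta_d <- array(rnorm(C1 * k * k), c(C1, k, k))
  theta_p <- matrix(rnorm(C1 * C2), C1, C2)
  got <- apply_sepconv(x, theta_d, theta_p)
  # equivalent standard kernel: K[c,dh,dw,o] = theta_d[c,dh,dw]*theta_p[c,o]
  K <- array(0, c(C1, k, k, C2))
  for (c in seq_len(C1)) for (o in seq_len(C2))
    K[c, , , o] <- theta_d[c, , ] * theta_p[c, o]
  want <- naive_conv2d(x[, , , 1], K, pad = 1L)
  expect_lt(max(abs(got[, , , 1] - want)), 1e-6)
})

test_that("the forward convolution agrees with the brute-force oracle", {
  set.seed(12)
  x <- array(runif(3 * 7 * 7), c(3, 7, 7, 2))
  w <- array(rnorm(3 * 9 * 4), c(3, 3, 3, 4))
  got <- dermlight:::conv_forward(x, w, pad = 1L)$out
  for (n in 1:2)
    expect_lt(max(abs(got[, , , n] - naive_conv2d(x[, , , n], w, pad = 1L))),
              1e-10)
})

test_that("spark modules concatenate expand paths and count parameters", {
  sc <- spark_config(64, 16, 64, 64)
  expect_equal(sc$out_channels, 128L)
  expect_error(spark_config(64, 200, 64, 64), "squeeze")
  sp <- with_seed_helper(1, build_spark(sc))
  x <- array(runif(64 * 4 * 4 * 2), c(64, 4, 4, 2))
  out <- dermlight:::spark_forward(sp, x, training = FALSE)
  expect_equal(dim(out$out), c(128L, 4L, 4L, 2L))
  # hand parameter sum from the per-layer primitives
  hand <- conv_param_count("pointwise", 64, 16, batchnorm = TRUE) +
    conv_param_count("pointwise", 16, 64, batchnorm = TRUE) +
    conv_param_count("depthwise", 16, kernel = 3, batchnorm = TRUE) +
    conv_param_count("pointwise", 16, 64, batchnorm = TRUE)
  got <- sum(vapply(dermlight:::collect_params(
    list(layers = list(sp))), length, integer(1)))
  expect_equal(got, hand)
  # the fire-module equivalent (standard 3x3 expand) holds more parameters
  fire_e3 <- conv_param_count("standard", 16, 64, 3)
  spark_e3 <- conv_param_count("separable", 16, 64, 3)
  expect_lt(spark_e3, fire_e3)
})

test_that("built networks classify, normalize and tap activations", {
  cfg <- network_config(input_size = 32, width_multiplier = 0.25)
  net <- build_network(cfg, seed = 3)
  set.seed(13)
  x <- array(runif(3 * 32 * 32 * 2), c(3, 32, 32, 2))
  out <- net_forward(net, x)
  expect_equal(dim(out$probabilities), c(2L, 9L))
  expect_equal(rowSums(out$probabilities), c(1, 1), tolerance = 1e-6)
  # deterministic inference
  out2 <- net_forward(net, x)
  expect_identical(out$probabilities, out2$probabilities)
  # tap on the last spark: E1 + E3 channels
  tap <- net_forward(net, x, tap_points = "spark8")$taps$spark8
  s8 <- cfg$sparks[[8]]
  expect_equal(dim(tap)[1], s8[2] + s8[3])
  expect_error(net_forward(net, array(0, c(3, 16, 16, 1))), "geometry")
})

test_that("ledger and backend parameter counts agree on random configs", {
  set.seed(14)
  for (i in 1:10) {
    sparks <- lapply(1:8, function(j) {
      s <- sample(c(8L, 16L, 24L), 1)
      e <- sample(c(16L, 32L, 40L), 2, replace = TRUE)
      c(s, e)
    })
    cfg <- network_config(input_size = 32,
                          stem_channels = sample(c(8L, 16L, 24L), 1),
                          sparks = sparks,
                          num_classes = sample(2:9, 1),
                          use_batchnorm = sample(c(TRUE, FALSE), 1))
    net <- build_network(cfg, seed = i)
    pr <- count_parameters(net)
    expect_identical(attr(pr, "total_params"), attr(pr, "backend_params"))
    expect_equal(sum(pr$param_count), attr(pr, "total_params"))
  }
})

test_that("parameter totals grow monotonically with the width multiplier", {
  widths <- c(0.25, 0.5, 0.75, 1, 1.5, 2)
  totals <- vapply(widths, function(w)
    attr(count_parameters(network_config(width_multiplier = w)),
         "total_params") * 1.0, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("FLOP accounting follows the documented closed forms", {
  # a single pointwise layer: 2 * H * W * C1 * C2 (+ head/stem framing)
  cfg <- network_config(input_size = 64, width_multiplier = 0.25)
  led <- count_parameters(cfg)
  sq1 <- led[led$name == "spark1.sq", ]
  s <- 64 / 4  # stem stride 2 + first pool
  expect_equal(sq1$flop_count,
               2 * s * s * cfg$stem_channels * cfg$sparks[[1]][1])
  # spark cheaper than its fire equivalent at equal channels
  spark_macs <- 9 * 16 + 16 * 64           # sepconv per position
  fire_macs <- 16 * 64 * 9                 # standard 3x3 per position
  expect_lt(spark_macs, fire_macs)
  expect_gt(count_flops(cfg, input_size = 128), count_flops(cfg))
})

test_that("calibration hits the parameter budget exactly and is frozen", {
  cfg <- calibrate_network_plan(3182412L)
  expect_identical(attr(count_parameters(cfg), "total_params"), 3182412L)
  def <- network_config()
  expect_identical(def$stem_channels, cfg$stem_channels)
  expect_identical(def$sparks, cfg$sparks)
  # other budgets are reachable too
  cfg2 <- calibrate_network_plan(500000L)
  expect_identical(attr(count_parameters(cfg2), "total_params"), 500000L)
})
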