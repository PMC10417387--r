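test_that("compute_hue matches its defining cases", {
  expect_equal(compute_hue(0.4, 0.4, 0.4), 0)            # achromatic
  expect_equal(compute_hue(1, 0, 0), 0)                   # pure red origin
  expect_equal(compute_hue(0, 0, 1), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(compute_hue(0, 1, 0), acos(-0.5), tolerance = 1e-12)
  # near-achromatic spread below epsilon collapses to hue 0
  expect_equal(compute_hue(0.5, 0.5, 0.5 + 1e-12), 0)
  # vectorized and bounded
  set.seed(1)
  h <- compute_hue(runif(500), runif(500), runif(500))
  expect_all_in_range(h, 0, 2 * pi)
})

test_that("hue is invariant under positive scaling and gray shifts", {
  set.seed(2)
  r <- runif(200, 0.1, 0.8); g <- runif(200, 0.1, 0.8)
  b <- runif(200, 0.1, 0.8)
  h0 <- compute_hue(r, g, b)
  a <- runif(200, 0.2, 1.2); t <- runif(200, 0, 0.1)
  h1 <- compute_hue(a * r + t, a * g + t, a * b + t)
  keep <- pmax(r, g, b) - pmin(r, g, b) > 1e-3
  expect_lt(max(abs(h1[keep] - h0[keep])), 1e-9)
})

test_that("CIECAM02 forward reproduces the published worked example", {
  vc <- ciecam02_viewing(white_xyz = c(95.05, 100, 108.88), la = 318.31,
                         yb = 20, surround = "average",
                         discount_illuminant = FALSE)
  out <- ciecam02_forward(matrix(c(19.01, 20, 21.78), 3, 1), vc)
  expect_equal(out$J, 41.731, tolerance = 1e-4)
  expect_equal(out$C, 0.1047, tolerance = 1e-3)
  expect_equal(out$h, 219.0484, tolerance = 1e-5)
})

test_that("white maps to full lightness / zero chroma and black to J = 0", {
  jch <- rgb_to_jch(rgb_image(array(1, c(2, 2, 3))))
  expect_lt(max(abs(jch$J_plane - 100)), 0.01)
  expect_lt(max(jch$C_plane), 0.05)
  jch0 <- rgb_to_jch(rgb_image(array(0, c(2, 2, 3))))
  expect_lt(max(jch0$J_plane), 1e-6)
  # normalized planes carry the stated constants
  expect_equal(jch$hn_plane, jch$h_plane / 15)
  expect_equal(jch$Jn_plane, jch$J_plane / 100 / 0.43)
})

test_that("CIECAM02 round-trips in-gamut pixels through the inverse model", {
  img <- random_image(6, 6, seed = 3)
  jch <- rgb_to_jch(img)
  back <- jch_to_rgb(jch)
  expect_lt(max(abs(back - img)), 1e-4)
})

test_that("invalid viewing conditions are rejected", {
  expect_error(ciecam02_viewing(la = -1), "positive")
  expect_error(rgb_to_jch(random_image(4), viewing = list()), "viewing")
})

test_that("global_stretch spans [0,1] and preserves order", {
  img <- array(60 / 255, c(3, 3, 3))
  img[1, 1, 1] <- 10 / 255; img[3, 3, 3] <- 110 / 255
  out <- global_stretch(rgb_image(img))
  expect_equal(out[2, 2, 2], 0.5, tolerance = 1e-12)
  expect_equal(min(out), 0); expect_equal(max(out), 1)
  # identity when endpoints already attained
  img2 <- random_image(5, 5, seed = 4); img2[1] <- 0; img2[2] <- 1
  expect_equal(global_stretch(img2), img2)
  # affine: rank order unchanged
  img3 <- random_image(6, 6, seed = 5)
  expect_equal(order(global_stretch(img3)), order(img3))
  # degenerate constant image
  expect_warning(z <- global_stretch(rgb_image(array(0.3, c(2, 2, 3)))),
                 "constant")
  expect_true(all(z == 0))
})

test_that("intensity plane uses the luma weights", {
  expect_equal(rgb_to_intensity(rgb_image(array(1, c(1, 1, 3))))[1, 1], 1)
  px <- array(0, c(1, 1, 3)); px[1, 1, 1] <- 1
  expect_equal(rgb_to_intensity(rgb_image(px))[1, 1], 0.299)
  px2 <- array(c(0.6, 0.3, 0.3), c(1, 1, 3))
  expect_equal(rgb_to_intensity(rgb_image(px2))[1, 1], 0.3897,
               tolerance = 1e-12)
  # weights sum to one: gray value v maps to v
  for (v in seq(0, 1, 0.1))
    expect_equal(rgb_to_intensity(rgb_image(array(v, c(1, 1, 3))))[1, 1], v,
                 tolerance = 1e-12)
})

test_that("global sigmoid map is centered and monotone; fusion stays in range", {
  cfg <- enhance_config(sigmoid_gain = 8, sigmoid_cutoff = 0.5)
  J <- matrix(seq(0, 1, length.out = 256), 16, 16)
  gg <- dermlight:::sigmoid_global_map(J, 8, 0.5)
  expect_equal(dermlight:::sigmoid_global_map(matrix(0.5, 1, 1), 8, 0.5)[1, 1],
               0.5, tolerance = 1e-12)
  expect_true(all(diff(sort(as.vector(gg))) >= 0))
  expect_true(all(diff(gg[order(J)]) >= 0))  # monotone in J
  gi <- enhance_intensity(J, NULL, cfg)
  expect_all_in_range(gi, 0, 1)
  # constant plane: local falls back to global, GI constant
  Jc <- matrix(0.4, 16, 16)
  gic <- enhance_intensity(Jc, NULL, cfg)
  expect_equal(max(gic) - min(gic), 0)
  # oversized tile grid errors with the offending dimension
  expect_error(enhance_intensity(matrix(0.5, 4, 16), NULL, cfg), "rows")
  expect_error(enhance_intensity(matrix(0.5, 16, 4), NULL, cfg), "cols")
})

test_that("hue-preserving reconstruction matches hand-computed branches", {
  xp <- rgb_image(array(c(0.6, 0.3, 0.3), c(1, 1, 3)))
  J <- matrix(0.3897, 1, 1)
  lo <- hue_preserving_reconstruct(xp, J, matrix(0.2, 1, 1))
  expect_equal(as.vector(lo), c(0.30792, 0.15396, 0.15396),
               tolerance = 1e-4)
  hi <- hue_preserving_reconstruct(xp, J, matrix(0.6, 1, 1))
  expect_equal(as.vector(hi), c(0.73783, 0.54121, 0.54121),
               tolerance = 1e-4)
  # hue of both outputs equals input hue
  h0 <- compute_hue(0.6, 0.3, 0.3)
  expect_equal(compute_hue(lo[1, 1, 1], lo[1, 1, 2], lo[1, 1, 3]), h0,
               tolerance = 1e-9)
  expect_equal(compute_hue(hi[1, 1, 1], hi[1, 1, 2], hi[1, 1, 3]), h0,
               tolerance = 1e-9)
  # GI = J is the identity
  img <- random_image(8, 8, seed = 6)
  J8 <- rgb_to_intensity(img)
  expect_equal(hue_preserving_reconstruct(img, J8, J8), img,
               tolerance = 1e-12)
})

test_that("the two reconstruction branches agree at GI = J", {
  set.seed(7)
  x <- runif(500); J <- runif(500, 0.05, 0.95)
  scale_branch <- x * (J / J)
  shift_branch <- (1 - J) / (1 - J) * (x - J) + J
  expect_lt(max(abs(scale_branch - shift_branch)), 1e-9)
})

test_that("enhance_image keeps grayscale rays, range and determinism", {
  g <- matrix(seq(0.1, 0.9, length.out = 256), 16, 16)
  img <- rgb_image(array(rep(g, 3), c(16, 16, 3)))
  out <- enhance_image(img, enhance_config(tile_grid = c(4L, 4L)))
  expect_lt(max(abs(out[, , 1] - out[, , 2])), 1e-9)
  expect_lt(max(abs(out[, , 1] - out[, , 3])), 1e-9)
  expect_all_in_range(out, 0, 1)
  lesion <- synth_image("NV", 64, seed = 5)
  e1 <- enhance_image(lesion)
  e2 <- enhance_image(lesion)
  expect_identical(e1, e2)
  expect_all_in_range(e1, 0, 1)
  # roi crop keeps geometry
  e3 <- enhance_image(lesion, enhance_config(roi_mode = "center_crop",
                                             roi_fraction = 0.8))
  expect_equal(dim(e3), dim(lesion))
})
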