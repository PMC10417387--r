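test_that("class weights are inverse frequencies averaging one", {
  m <- random_manifest(90, seed = 20)
  m$label <- rep(psl_classes(), each = 10)
  expect_equal(unname(class_weights(m)), rep(1, 9))

  m2 <- data.frame(label = rep(c("A", "B"), c(90, 10)))
  w <- class_weights(m2, classes = c("A", "B"))
  expect_equal(unname(w), c(100 / 180, 100 / 20), tolerance = 1e-12)

  m3 <- generate_manifest(1, seed = 1)
  expect_equal(unname(class_weights(m3)["NV"]), 24000 / (9 * 12000),
               tolerance = 1e-12)
  m4 <- data.frame(label = rep("NV", 5))
  expect_error(class_weights(m4), "absent")
})

test_that("weighted cross-entropy matches its closed forms", {
  p_perfect <- diag(9)[1:3, ]
  expect_lt(weighted_cross_entropy(p_perfect, 1:3), 1e-10)
  p_unif <- matrix(1 / 9, 4, 9)
  expect_equal(weighted_cross_entropy(p_unif, c(1, 3, 5, 9)), log(9),
               tolerance = 1e-12)
  # linear in the weights
  set.seed(21)
  p <- matrix(runif(36), 4, 9); p <- p / rowSums(p)
  y <- c(2, 4, 6, 8)
  w <- runif(9, 0.5, 2)
  expect_equal(weighted_cross_entropy(p, y, 2 * w),
               2 * weighted_cross_entropy(p, y, w), tolerance = 1e-12)
  # unit weights reduce to plain cross-entropy
  expect_equal(weighted_cross_entropy(p, y),
               mean(-log(p[cbind(1:4, y)])), tolerance = 1e-12)
  expect_error(weighted_cross_entropy(p, 1:3), "batch size")
})

test_that("AdaBelief reproduces the hand-derived single step", {
  st <- adabelief_init(1, lr = 1e-3)
  up <- adabelief_step(1, 1, st)
  # m1 = 0.1, m_hat = 1; s1 = 0.001*0.81, s_hat = 0.81
  expect_equal(up$params, 1 - 1e-3 / (0.9 + 1e-8), tolerance = 1e-9)
  expect_equal(up$params, 0.9988889, tolerance = 1e-7)
  expect_equal(up$state$t, 1L)
  # zero gradient from zero state leaves parameters untouched
  st0 <- adabelief_init(c(a = 2, b = -3))
  up0 <- adabelief_step(c(a = 2, b = -3), c(a = 0, b = 0), st0)
  expect_equal(up0$params, c(a = 2, b = -3))
})

test_that("AdaBelief drives a convex quadratic to the optimum", {
  theta <- 1; st <- adabelief_init(theta, lr = 1e-2)
  vals <- numeric(0)
  for (i in 1:5000) {
    up <- adabelief_step(theta, theta, st)  # f = theta^2/2, g = theta
    theta <- up$params; st <- up$state
    vals[i] <- abs(theta)
    if (abs(theta) < 1e-3) break
  }
  expect_lt(abs(theta), 1e-3)
  expect_lte(length(vals), 5000)
})

test_that("stratified folds cover, are disjoint and balanced", {
  m <- random_manifest(90, seed = 22)
  m$label <- rep(psl_classes(), each = 10)
  folds <- kfold_split(m, k = 10, seed = 1)
  expect_equal(sort(unlist(folds)), 1:90)
  for (f in folds) {
    expect_equal(length(f), 9L)
    expect_equal(sort(m$label[f]), sort(psl_classes()))
  }
  expect_identical(kfold_split(m, 10, seed = 1), folds)
  expect_error(kfold_split(m, 1), "at least 2")
  expect_error(kfold_split(m, 91), "exceeds")
  w <- capture_warnings(kfold_split(generate_manifest(0.001, 1), k = 3,
                                    seed = 1))
  expect_match(w, "fewer records", all = TRUE)
})

test_that("fold properties hold across random manifests", {
  for (s in 1:50) {
    set.seed(s)
    n <- sample(30:120, 1)
    k <- sample(2:5, 1)
    m <- random_manifest(n, labels = sample(psl_classes(), 4), seed = s)
    folds <- suppressWarnings(kfold_split(m, k, seed = s))
    expect_equal(sort(unlist(folds)), seq_len(n))
    expect_equal(sum(lengths(folds)), n)
    # per-class proportions preserved within one record
    for (lab in unique(m$label)) {
      per_fold <- vapply(folds, function(f) sum(m$label[f] == lab),
                         numeric(1))
      expect_lte(max(per_fold) - min(per_fold), 1)
    }
  }
})

test_that("the step schedule halves the rate every period", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 1e-3)
  expect_equal(lr_at(10, cfg), 5e-4)
  expect_equal(lr_at(39, cfg), 1.25e-4)
  expect_equal(lr_at(9, cfg), 1e-3)
})

test_that("an untrained network starts near the uniform loss", {
  cfg <- network_config(input_size = 32, width_multiplier = 0.25)
  net <- build_network(cfg, seed = 5)
  set.seed(23)
  labs <- rep(psl_classes(), 2)
  imgs <- lapply(seq_along(labs),
                 function(i) synth_image(labs[i], 32, seed = i))
  x <- dermlight:::images_to_tensor(imgs)
  fw <- dermlight:::network_forward(net, x, training = FALSE)
  probs <- t(dermlight:::softmax_cols(fw$logits))
  loss <- weighted_cross_entropy(probs, match(labs, psl_classes()))
  expect_lt(abs(loss - log(9)), 0.3)
})

test_that("short training runs are recorded and deterministic", {
  labs <- rep(psl_classes(), each = 2)
  imgs <- lapply(seq_along(labs),
                 function(i) synth_image(labs[i], 32, seed = 100 + i))
  x <- dermlight:::images_to_tensor(imgs)
  y <- match(labs, psl_classes())
  cfg <- network_config(input_size = 32, width_multiplier = 0.25)
  tc <- train_config(epochs = 2, batch_size = 6, seed = 9)
  r1 <- train_network(build_network(cfg, seed = 4), x, y, tc)
  expect_equal(nrow(r1$history), 2L)
  expect_true(all(is.finite(r1$history$loss)))
  expect_true(all(c("loss", "accuracy", "macro_recall", "macro_auc") %in%
                    names(r1$history)))
  r2 <- train_network(build_network(cfg, seed = 4), x, y, tc)
  expect_equal(r1$history, r2$history)
})
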