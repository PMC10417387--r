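test_that("confusion matrices count true-by-predicted pairs", {
  labs <- c("NV", "NV", "MEL", "BCC")
  cm <- confusion(labs, labs)
  expect_true(all(cm[row(cm) != col(cm)] == 0))
  expect_equal(sum(diag(cm)), 4)

  cm2 <- confusion(rep("NV", 3), rep("MEL", 3))
  expect_equal(cm2["NV", "MEL"], 3)
  expect_equal(sum(cm2), 3)

  set.seed(30)
  t <- sample(psl_classes(), 200, replace = TRUE)
  p <- sample(psl_classes(), 200, replace = TRUE)
  cm3 <- confusion(t, p)
  for (lab in psl_classes())
    expect_equal(sum(cm3[lab, ]), sum(t == lab))
  expect_error(confusion(c("NV", "??"), c("NV", "NV")), "unknown")
  expect_error(confusion("NV", c("NV", "NV")), "equal length")
})

test_that("one-vs-rest reduction conserves the total", {
  m <- matrix(c(30, 20, 10, 40), 2, 2, byrow = TRUE)
  bc <- binary_counts(m, 1)
  expect_equal(bc, list(TP = 30, TN = 40, FP = 10, FN = 20))
  set.seed(31)
  r <- matrix(sample(0:30, 81, replace = TRUE), 9, 9)
  for (i in 1:9) {
    b <- binary_counts(r, i)
    expect_equal(b$TP + b$TN + b$FP + b$FN, sum(r))
  }
  d <- diag(5)
  for (i in 1:5) {
    b <- binary_counts(d, i)
    expect_equal(b$FP, 0); expect_equal(b$FN, 0)
  }
})

test_that("binary metrics evaluate the worked case and conventions", {
  perfect <- binary_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(perfect), rep(1, 6))

  m <- binary_metrics(list(TP = 30, TN = 40, FP = 10, FN = 20))
  expect_equal(m[["ACC"]], 0.70, tolerance = 1e-12)
  expect_equal(m[["PR"]], 0.75, tolerance = 1e-12)
  expect_equal(m[["RC"]], 0.60, tolerance = 1e-12)
  expect_equal(m[["SP"]], 0.80, tolerance = 1e-12)
  expect_equal(m[["F1"]], 2 / 3, tolerance = 1e-10)
  expect_equal(m[["MCC"]], 1000 / sqrt(6e6), tolerance = 1e-12)
  expect_equal(round(m[["MCC"]], 4), 0.4082)

  degenerate <- binary_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_equal(degenerate[["PR"]], 0)
  expect_equal(degenerate[["MCC"]], 0)
})

test_that("metrics agree with the brute-force oracle on random matrices", {
  set.seed(32)
  for (rep in 1:300) {
    m <- matrix(rpois(81, sample(c(0.5, 3, 20), 1)), 9, 9)
    i <- sample(9, 1)
    got <- binary_metrics(binary_counts(m, i))
    want <- oracle_class_metrics(m, i)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("MCC stays in [-1, 1] and attains 1 only without errors", {
  set.seed(33)
  for (rep in 1:200) {
    cnt <- as.list(stats::setNames(sample(0:40, 4, replace = TRUE),
                                   c("TP", "TN", "FP", "FN")))
    mcc <- binary_metrics(cnt)[["MCC"]]
    expect_gte(mcc, -1); expect_lte(mcc, 1)
    if (cnt$FP == 0 && cnt$FN == 0 && cnt$TP > 0 && cnt$TN > 0)
      expect_equal(mcc, 1)
  }
})

test_that("macro report averages the per-class columns", {
  d <- diag(c(5, 3, 7, 2, 9, 4, 6, 1, 8))
  rownames(d) <- colnames(d) <- psl_classes()
  rep0 <- macro_report(d)
  expect_equal(unname(rep0$macro), rep(1, 6))
  expect_equal(rep0$top1_accuracy, 1)

  set.seed(34)
  r <- matrix(rpois(81, 5), 9, 9,
              dimnames = list(psl_classes(), psl_classes()))
  mr <- macro_report(r)
  expect_equal(unname(mr$macro["MCC"]), mean(mr$per_class$MCC))
  expect_equal(unname(mr$macro["F1"]), mean(mr$per_class$F1))
  expect_equal(mr$n, sum(r))
})

test_that("one-vs-rest AUC is rank-based with the usual symmetries", {
  # perfectly separating scores
  labs <- rep(c("NV", "MEL"), each = 10)
  sc <- matrix(0, 20, 9, dimnames = list(NULL, psl_classes()))
  sc[, "NV"] <- c(seq(0.6, 0.9, length.out = 10),
                  seq(0.1, 0.4, length.out = 10))
  sc[, "MEL"] <- 1 - sc[, "NV"]
  a <- suppressWarnings(auc_ovr(sc, labs))
  expect_equal(unname(a$per_class["NV"]), 1)
  expect_equal(unname(a$per_class["MEL"]), 1)

  # reversal maps AUC to 1 - AUC; constant scores give exactly 0.5
  set.seed(35)
  labs2 <- sample(c("NV", "MEL"), 100, replace = TRUE)
  s2 <- matrix(runif(900), 100, 9, dimnames = list(NULL, psl_classes()))
  a2 <- suppressWarnings(auc_ovr(s2, labs2))
  a2r <- suppressWarnings(auc_ovr(-s2, labs2))
  expect_equal(unname(a2$per_class["NV"] + a2r$per_class["NV"]), 1,
               tolerance = 1e-12)
  s_const <- matrix(0.5, 100, 9, dimnames = list(NULL, psl_classes()))
  ac <- suppressWarnings(auc_ovr(s_const, labs2))
  expect_equal(unname(ac$per_class["NV"]), 0.5)

  # independent labels: null AUC near 0.5
  set.seed(36)
  labs3 <- sample(psl_classes(), 5000, replace = TRUE)
  s3 <- matrix(runif(45000), 5000, 9,
               dimnames = list(NULL, psl_classes()))
  a3 <- auc_ovr(s3, labs3)
  expect_lt(abs(a3$macro - 0.5), 0.03)

  # absent class: NA with a warning, excluded from the macro
  expect_warning(a4 <- auc_ovr(s2, labs2), "absent")
  expect_true(is.na(a4$per_class[["DF"]]))
  expect_false(is.na(a4$macro))
})

test_that("rank AUC matches the pROC reference on a random case", {
  skip_if_not_installed("pROC")
  set.seed(37)
  labs <- sample(c("NV", "MEL"), 80, replace = TRUE)
  sc <- matrix(runif(720), 80, 9, dimnames = list(NULL, psl_classes()))
  got <- suppressWarnings(auc_ovr(sc, labs))$per_class[["NV"]]
  ref <- as.numeric(pROC::auc(pROC::roc(labs == "NV", sc[, "NV"],
                                        levels = c(FALSE, TRUE),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})
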