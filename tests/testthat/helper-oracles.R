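# Independent oracles used across the test files. These are deliberately
# naive (loops, direct formula evaluation) and share no code with the
# implementation they check.

# Direct evaluation of a standard 2D convolution (valid for stride 1,
# symmetric zero padding). x: (C1, H, W); w: (C1, k, k, C2).
naive_conv2d <- function(x, w, pad = 0L) {
  C1 <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  k <- dim(w)[2]; C2 <- dim(w)[4]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  xp <- array(0, c(C1, Hp, Wp))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  Ho <- Hp - k + 1L; Wo <- Wp - k + 1L
  out <- array(0, c(C2, Ho, Wo))
  for (o in seq_len(C2))
    for (i in seq_len(Ho))
      for (j in seq_len(Wo)) {
        acc <- 0
        for (c in seq_len(C1))
          for (dh in seq_len(k))
            for (dw in seq_len(k))
              acc <- acc + w[c, dh, dw, o] * xp[c, i + dh - 1L, j + dw - 1L]
        out[o, i, j] <- acc
      }
  out
}

# Brute-force one-vs-rest metrics for class `ci` of a confusion matrix:
# expand the matrix into label/prediction vectors, count the four
# outcomes by explicit comparison, and evaluate the definitions.
oracle_class_metrics <- function(m, ci) {
  k <- nrow(m)
  truth <- integer(0); pred <- integer(0)
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      truth <- c(truth, rep(i, m[i, j]))
      pred <- c(pred, rep(j, m[i, j]))
    }
  tp <- as.numeric(sum(truth == ci & pred == ci))
  fn <- as.numeric(sum(truth == ci & pred != ci))
  fp <- as.numeric(sum(truth != ci & pred == ci))
  tn <- as.numeric(sum(truth != ci & pred != ci))
  div <- function(a, b) if (b > 0) a / b else 0
  acc <- div(tp + tn, tp + tn + fp + fn)
  pr <- div(tp, tp + fp)
  rc <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  c(ACC = acc, PR = pr, RC = rc, SP = sp, F1 = f1, MCC = mcc)
}

# random manifest-like data frame over a label subset
random_manifest <- function(n, labels = psl_classes(), seed = 1L) {
  set.seed(seed)
  df <- data.frame(path = sprintf("img/%05d.png", seq_len(n)),
                   label = sample(labels, n, replace = TRUE),
                   origin = "synthetic", stringsAsFactors = FALSE)
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

# random (H, W, 3) image in [0, 1]
random_image <- function(h = 32L, w = h, seed = 1L) {
  set.seed(seed)
  rgb_image(array(runif(h * w * 3), c(h, w, 3)))
}

with_seed_helper <- function(seed, code) {
  set.seed(seed)
  force(code)
}

expect_all_in_range <- function(x, lo, hi) {
  expect_gte(min(x), lo)
  expect_lte(max(x), hi)
}
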