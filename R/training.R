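#' Training configuration
#'
#' Optimization defaults: AdaBelief with learning rate `1e-3`, mini-batch
#' size 16, 40 epochs, a step learning-rate policy that halves the rate
#' every `step_period` epochs (`gamma = 0.5`), 10-fold stratified
#' cross-validation, and weighted cross-entropy loss.
#'
#' @param epochs number of training epochs.
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param gamma multiplicative step-schedule factor in `(0, 1]`.
#' @param step_period epochs between schedule steps.
#' @param k_folds folds for cross-validation.
#' @param weight_decay decoupled weight decay coefficient (0 disables).
#' @param early_stopping_patience epochs without validation-loss
#'   improvement before stopping (`Inf` disables; the default).
#' @param seed integer seed for shuffling and dropout.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 40L, batch_size = 16L, lr = 1e-3,
                         gamma = 0.5, step_period = 10L, k_folds = 10L,
                         weight_decay = 0, early_stopping_patience = Inf,
                         seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, gamma > 0, gamma <= 1,
            lr > 0, step_period >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 gamma = gamma, step_period = as.integer(step_period),
                 k_folds = as.integer(k_folds),
                 weight_decay = weight_decay,
                 early_stopping_patience = early_stopping_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' `weight_c = total / (num_classes * count_c)`, so the weights average 1
#' on a balanced manifest and up-weight rare classes in proportion to
#' their scarcity.
#'
#' @param manifest a `dataset_manifest` (or any data frame with a
#'   `label` column over [psl_classes()]).
#' @param classes label set; every class must be present.
#' @return named numeric weights.
#' @export
class_weights <- function(manifest, classes = psl_classes()) {
  counts <- table(factor(manifest$label, levels = classes))
  missing <- names(counts)[counts == 0]
  if (length(missing))
    stop("class absent from manifest: ", paste(missing, collapse = ", "))
  w <- nrow(manifest) / (length(classes) * as.numeric(counts))
  stats::setNames(w, classes)
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of `-w[y] * log p[y]`, with probabilities floored
#' at `1e-12`. With unit weights this is the ordinary cross-entropy; the
#' loss is linear in the weights.
#'
#' @param probabilities `N x K` matrix of class probabilities (rows sum
#'   to 1).
#' @param labels integer class indices in `1..K` (or factor/character
#'   over `colnames`).
#' @param weights per-class weights (default all 1).
#' @return non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(probabilities, labels,
                                   weights = rep(1, ncol(probabilities))) {
  k <- ncol(probabilities)
  if (is.character(labels) || is.factor(labels))
    labels <- match(as.character(labels), colnames(probabilities))
  labels <- as.integer(labels)
  if (length(labels) != nrow(probabilities))
    stop("labels length (", length(labels),
         ") does not match batch size (", nrow(probabilities), ")")
  if (length(weights) != k)
    stop("expected ", k, " class weights, got ", length(weights))
  p <- pmax(probabilities[cbind(seq_along(labels), labels)], 1e-12)
  mean(-weights[labels] * log(p))
}

#' AdaBelief optimizer
#'
#' Adapts the step size to the "belief" in the current gradient: the
#' first moment `m` tracks an exponential moving average of the gradient
#' (the prediction), and the second moment `s` tracks the EMA of the
#' squared deviation `(g - m)^2` from that prediction. Both are
#' bias-corrected, and the update is
#' `theta <- theta - lr * m_hat / (sqrt(s_hat) + eps)`; epsilon enters
#' the denominator only. A gradient close to its prediction yields a
#' small `s` and hence a confident, large step.
#'
#' @param params named list of numeric arrays (or a single array).
#' @param lr learning rate.
#' @param beta1,beta2 EMA decay rates of `m` and `s`.
#' @param eps denominator floor.
#' @return `adabelief_init()` returns an optimizer state.
#' @export
adabelief_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  single <- !is.list(params)
  if (single) params <- list(theta = params)
  state <- list(m = lapply(params, function(p) p * 0),
                s = lapply(params, function(p) p * 0),
                t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                single = single)
  class(state) <- "adabelief_state"
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn adabelief_init one optimizer step; returns
#'   `list(params, state)`.
#' @param grads gradients matching `params` in shape.
#' @param state an `adabelief_state`.
#' @param lr_override optional learning rate for this step (schedules).
#' @export
adabelief_step <- function(params, grads, state, lr_override = NULL) {
  single <- state$single
  if (single) { params <- list(theta = params); grads <- list(theta = grads) }
  lr <- lr_override %||% state$lr
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    m <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    s <- state$beta2 * state$s[[nm]] + (1 - state$beta2) * (g - m)^2
    state$m[[nm]] <- m
    state$s[[nm]] <- s
    step <- lr * (m / bc1) / (sqrt(s / bc2) + state$eps)
    params[[nm]] <- params[[nm]] - step
  }
  if (single) params <- params$theta
  list(params = params, state = state)
}

#' Learning rate at a given epoch under the step schedule
#'
#' `lr * gamma ^ floor(epoch / step_period)` with the configured base
#' rate; epochs are counted from 0.
#'
#' @param epoch non-negative epoch index.
#' @param config a [train_config()].
#' @return learning rate.
#' @export
lr_at <- function(epoch, config = train_config()) {
  stopifnot(epoch >= 0)
  config$lr * config$gamma^(epoch %/% config$step_period)
}

#' Stratified k-fold split of a manifest
#'
#' Assigns every record to one of `k` folds, shuffling within each class
#' (seeded) and dealing records round-robin so per-class proportions are
#' preserved within one record. Classes rarer than `k` records cannot
#' appear in every fold; a warning reports them.
#'
#' @param manifest a `dataset_manifest`.
#' @param k number of folds (at least 2).
#' @param seed integer seed.
#' @return list of `k` disjoint integer index vectors covering the
#'   manifest.
#' @export
kfold_split <- function(manifest, k = 10L, seed = 1L) {
  n <- nrow(manifest)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of records (", n, ")")
  fold_of <- integer(n)
  with_seed(derive_seed(seed, 31L), {
    for (lab in unique(manifest$label)) {
      idx <- which(manifest$label == lab)
      if (length(idx) < k)
        warning("class ", lab, " has fewer records (", length(idx),
                ") than folds (", k, ")")
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) which(fold_of == f))
}

# gradient of the weighted cross-entropy w.r.t. logits (K x N)
wce_logit_grad <- function(probs, labels, weights) {
  n <- ncol(probs)
  onehot <- matrix(0, nrow(probs), n)
  onehot[cbind(labels, seq_len(n))] <- 1
  wv <- weights[labels]
  (probs - onehot) * rep(wv, each = nrow(probs)) / n
}

#' Train a network on an in-memory tensor
#'
#' Mini-batch AdaBelief training with weighted cross-entropy and the
#' step learning-rate schedule. Per-epoch history records training loss,
#' top-1 accuracy, macro recall and macro one-vs-rest AUC (computed from
#' the aggregated batch predictions), and the same metrics on an
#' optional validation set. A non-finite loss aborts with the offending
#' batch index.
#'
#' @param net a [build_network()] network.
#' @param x input tensor `(3, H, W, N)`.
#' @param y integer labels in `1..num_classes`.
#' @param config a [train_config()].
#' @param weights per-class loss weights (default unit).
#' @param x_val,y_val optional validation tensor and labels.
#' @param verbose print one line per epoch.
#' @return list with `net` (trained), `history` (one row per epoch).
#' @export
train_network <- function(net, x, y, config = train_config(),
                          weights = rep(1, net$config$num_classes),
                          x_val = NULL, y_val = NULL, verbose = FALSE) {
  n <- dim(x)[4]
  y <- as.integer(y)
  stopifnot(length(y) == n, all(y >= 1), all(y <= net$config$num_classes))
  params <- collect_params(net)
  opt <- adabelief_init(params, lr = config$lr)
  history <- list()
  with_seed(derive_seed(config$seed, 77L), {
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at(epoch, config)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; preds <- integer(n); scores <- matrix(0, n, net$config$num_classes)
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        xb <- x[, , , idx, drop = FALSE]
        fw <- network_forward(net, xb, training = TRUE, with_caches = TRUE)
        net <- fw$net
        probs <- softmax_cols(fw$logits)
        loss <- weighted_cross_entropy(t(probs), y[idx], weights)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch, ", batch ", bi)
        ep_loss <- ep_loss + loss * length(idx)
        preds[idx] <- apply(probs, 2L, which.max)
        scores[idx, ] <- t(probs)
        dlogits <- wce_logit_grad(probs, y[idx], weights)
        grads <- flatten_grads(network_backward(net, fw$caches, dlogits))
        params <- collect_params(net)
        upd <- adabelief_step(params, grads[names(params)], opt,
                              lr_override = lr)
        opt <- upd$state
        if (config$weight_decay > 0)  # decoupled decay, after the step
          upd$params <- lapply(upd$params,
                               function(p) p * (1 - lr * config$weight_decay))
        net <- assign_params(net, upd$params)
      }
      row <- data.frame(epoch = epoch, lr = lr, loss = ep_loss / n,
                        accuracy = mean(preds == y),
                        macro_recall = macro_recall_quick(y, preds,
                                                          net$config$num_classes),
                        macro_auc = macro_auc_quick(y, scores))
      if (!is.null(x_val)) {
        vfw <- network_forward(net, x_val, training = FALSE)
        vprobs <- softmax_cols(vfw$logits)
        vpred <- apply(vprobs, 2L, which.max)
        row$val_loss <- weighted_cross_entropy(t(vprobs), y_val, weights)
        row$val_accuracy <- mean(vpred == y_val)
      }
      history[[epoch + 1L]] <- row
      if (verbose)
        message(sprintf("epoch %d lr %.2e loss %.4f acc %.3f", epoch, lr,
                        row$loss, row$accuracy))
      if (!is.null(x_val) && is.finite(config$early_stopping_patience)) {
        losses <- vapply(history, function(r) r$val_loss, numeric(1))
        if (length(losses) - which.min(losses) >=
            config$early_stopping_patience) break
      }
    }
  })
  list(net = net, history = do.call(rbind, history))
}

macro_recall_quick <- function(y, pred, k) {
  rc <- vapply(seq_len(k), function(c) {
    n <- sum(y == c)
    if (n == 0) NA_real_ else sum(y == c & pred == c) / n
  }, numeric(1))
  mean(rc, na.rm = TRUE)
}

macro_auc_quick <- function(y, scores) {
  aucs <- vapply(seq_len(ncol(scores)), function(c) {
    pos <- y == c
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(scores[, c])
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
      (sum(pos) * sum(!pos))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Train from a manifest
#'
#' Materializes the manifest records (synthesizing and augmenting as
#' needed), optionally applies the hue-preserving enhancement to every
#' image, and trains the network.
#'
#' @param net a [build_network()] network.
#' @param manifest a `dataset_manifest`.
#' @param config a [train_config()].
#' @param enhance_config optional [enhance_config()]; `NULL` skips
#'   enhancement.
#' @param dir optional directory against which manifest paths resolve.
#' @param weights per-class loss weights; defaults to
#'   [class_weights()] when every class is present, else unit weights.
#' @param verbose print one line per epoch.
#' @return list with `net`, `history`, `labels` (the factor coding
#'   used).
#' @export
train_on_manifest <- function(net, manifest, config = train_config(),
                              enhance_config = NULL, dir = NULL,
                              weights = NULL, verbose = FALSE) {
  size <- net$config$input_size
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_record_image(manifest[i, , drop = FALSE], size = size,
                             dir = dir)
    if (!is.null(enhance_config)) img <- enhance_image(img, enhance_config)
    img
  })
  x <- images_to_tensor(images)
  y <- match(manifest$label, psl_classes())
  if (is.null(weights)) {
    weights <- if (all(psl_classes() %in% manifest$label))
      class_weights(manifest) else rep(1, net$config$num_classes)
  }
  out <- train_network(net, x, y, config, weights, verbose = verbose)
  out$labels <- psl_classes()
  out
}
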