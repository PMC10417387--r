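#' Experiment configuration
#'
#' Bundles every stage configuration with the dataset scale and a single
#' global seed. The global seed fans out to stage-specific seeds by
#' fixed offsets, so data generation, splitting, initialization and
#' training are each independently reproducible.
#'
#' @param scale manifest scale (see [generate_manifest()]).
#' @param seed global integer seed.
#' @param network a [network_config()].
#' @param train a [train_config()].
#' @param enhance an [enhance_config()] or `NULL` to skip enhancement.
#' @param augment an [augment_config()].
#' @param balance balance classes by augmentation before splitting.
#' @param k_folds folds to run (capped by `train$k_folds`).
#' @param out_dir optional output directory for reports and logs.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(scale = 0.005, seed = 1L,
                              network = network_config(),
                              train = train_config(),
                              enhance = NULL,
                              augment = augment_config(),
                              balance = FALSE, k_folds = train$k_folds,
                              out_dir = NULL) {
  structure(list(scale = scale, seed = as.integer(seed), network = network,
                 train = train, enhance = enhance, augment = augment,
                 balance = isTRUE(balance), k_folds = as.integer(k_folds),
                 out_dir = out_dir),
            class = "experiment_config")
}

exp_log <- function(config, stage, msg, level = "INFO") {
  line <- sprintf("%s [%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, stage,
                  msg)
  message(line)
  if (!is.null(config$out_dir)) {
    dir.create(file.path(config$out_dir, "logs"), recursive = TRUE,
               showWarnings = FALSE)
    cat(line, "\n", file = file.path(config$out_dir, "logs", "run.log"),
        append = TRUE)
  }
  invisible(line)
}

#' Enhance every image of a manifest
#'
#' Reads each record's image, applies [enhance_image()] and writes the
#' result as PNG under `out_dir`, returning the re-pathed manifest.
#' Unreadable records are skipped with a logged warning; the run
#' continues.
#'
#' @param manifest a `dataset_manifest` whose paths point at image
#'   files.
#' @param enhance_config an [enhance_config()].
#' @param out_dir output directory.
#' @param viewing CIECAM02 viewing conditions.
#' @return manifest of the successfully enhanced records.
#' @export
run_preprocess <- function(manifest, enhance_config = enhance_config(),
                           out_dir, viewing = ciecam02_viewing()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  keep <- logical(nrow(manifest))
  new_path <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, , drop = FALSE]
    out <- tryCatch({
      img <- read_image(rec$path)
      enhanced <- enhance_image(img, enhance_config, viewing)
      dest <- file.path(out_dir, paste0(
        tools::file_path_sans_ext(basename(rec$path)), "_enh.png"))
      write_image(enhanced, dest)
      dest
    }, error = function(e) {
      warning("skipping record ", rec$path, ": ", conditionMessage(e),
              call. = FALSE)
      NA_character_
    })
    keep[i] <- !is.na(out)
    new_path[i] <- out
  }
  res <- manifest[keep, , drop = FALSE]
  res$source_path <- manifest$path[keep]
  res$path <- new_path[keep]
  rownames(res) <- NULL
  res
}

#' Run a full cross-validated experiment
#'
#' Generates the manifest, optionally balances it, materializes images
#' in memory (enhancing if configured), then trains and evaluates the
#' network on each of the first `k_folds` stratified folds. Each fold's
#' held-out records yield a [macro_report()]; aggregate means over folds
#' and the network's parameter ledger are attached.
#'
#' @param config an [experiment_config()].
#' @return an `experiment_report`: list with `fold_reports`,
#'   `aggregate`, `param_report`, `history` (per fold), `config`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- Sys.time()
  exp_log(config, "synth", sprintf("generating manifest (scale %g, seed %d)",
                                   config$scale, config$seed))
  manifest <- generate_manifest(config$scale, derive_seed(config$seed, 1L))
  if (config$balance) manifest <- balance_classes(manifest, config$augment)

  size <- config$network$input_size
  exp_log(config, "images", sprintf("materializing %d images at %dx%d",
                                    nrow(manifest), size, size))
  images <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- load_record_image(manifest[i, , drop = FALSE], size = size,
                             config = config$augment)
    if (!is.null(config$enhance)) img <- enhance_image(img, config$enhance)
    img
  })
  x <- images_to_tensor(images)
  y <- match(manifest$label, psl_classes())
  weights <- tryCatch(class_weights(manifest),
                      error = function(e) rep(1, config$network$num_classes))

  folds <- kfold_split(manifest, config$train$k_folds,
                       derive_seed(config$seed, 2L))
  k_run <- min(config$k_folds, length(folds))
  fold_reports <- list(); histories <- list()
  for (f in seq_len(k_run)) {
    exp_log(config, "train", sprintf("fold %d/%d", f, k_run))
    hold <- folds[[f]]
    tr_idx <- setdiff(seq_len(nrow(manifest)), hold)
    net <- build_network(config$network, seed = derive_seed(config$seed, 3L + f))
    fold_cfg <- config$train
    fold_cfg$seed <- derive_seed(config$seed, 100L + f)
    res <- tryCatch(
      train_network(net, x[, , , tr_idx, drop = FALSE], y[tr_idx],
                    fold_cfg, weights),
      error = function(e) {
        exp_log(config, "train", conditionMessage(e), level = "ERROR")
        NULL
      })
    if (is.null(res)) next
    fw <- network_forward(res$net, x[, , , hold, drop = FALSE],
                          training = FALSE)
    probs <- t(softmax_cols(fw$logits))
    pred <- max.col(probs, ties.method = "first")
    cm <- confusion(psl_classes()[y[hold]], psl_classes()[pred])
    colnames(probs) <- psl_classes()
    rep_f <- suppressWarnings(
      macro_report(cm, scores = probs, labels = psl_classes()[y[hold]]))
    rep_f$fold <- f
    fold_reports[[f]] <- rep_f
    histories[[f]] <- res$history
  }
  if (!length(fold_reports)) stop("no fold completed successfully")
  done <- !vapply(fold_reports, is.null, logical(1))
  macro_mat <- do.call(rbind, lapply(fold_reports[done],
                                     function(r) r$macro))
  aggregate <- list(macro_means = colMeans(macro_mat),
                    top1_accuracy = mean(vapply(fold_reports[done],
                                                function(r) r$top1_accuracy,
                                                numeric(1))))
  report <- structure(
    list(fold_reports = fold_reports[done], aggregate = aggregate,
         param_report = count_parameters(config$network),
         history = histories[done], config = config,
         config_hash = config_hash(config),
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "experiment_report")
  if (!is.null(config$out_dir)) write_experiment_report(report)
  report
}

config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %%
            .Machine$integer.max)
}

write_experiment_report <- function(report) {
  dir <- file.path(report$config$out_dir, "reports")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  agg <- c(as.list(report$aggregate$macro_means),
           top1_accuracy = report$aggregate$top1_accuracy,
           n_folds = length(report$fold_reports),
           config_hash = report$config_hash,
           seed = report$config$seed)
  jsonlite::write_json(agg, file.path(dir, "aggregate.json"),
                       auto_unbox = TRUE, digits = NA)
  for (i in seq_along(report$fold_reports))
    utils::write.csv(report$fold_reports[[i]]$per_class,
                     file.path(dir, sprintf("fold%02d_metrics.csv", i)),
                     row.names = FALSE)
  invisible(report)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report:", length(x$fold_reports), "fold(s), config",
      x$config_hash, "\n")
  cat("Aggregate macro means:\n")
  print(round(x$aggregate$macro_means, 4))
  cat("Mean top-1 accuracy:", round(x$aggregate$top1_accuracy, 4), "\n")
  invisible(x)
}
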