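# End-to-end orchestration: Gaussian denoising -> (LBP branch, deep branch)
# -> fusion + entropy selection (fitted on the training split only) -> LSTM
# classifier -> held-out metrics. A run is fully determined by
# (config, seed, data); all stage seeds derive from config$seed.

#' Pipeline configuration
#'
#' Collects every stage's tunables. The full-scale defaults mirror the
#' published setup (227 px texture branch, 1186 retained features, 0.75
#' split); `small = TRUE` scales the run down for CPU tests (64 px branches,
#' a 64-feature backbone, 200 retained features).
#'
#' @param gaussian_sigma,gaussian_size Gaussian denoising kernel.
#' @param lbp_side resize side for the texture branch (default 227).
#' @param backbone a [backbone_spec()] for the deep branch.
#' @param keep_n fused features retained by entropy selection (default 1186).
#' @param lstm_hidden,lstm_step_width,lstm_fc_units LSTM classifier size.
#' @param train_fraction per-class training fraction (default 0.75).
#' @param backbone_epochs,classifier_epochs training epochs per model.
#' @param batch_size mini-batch size for both trainings.
#' @param label_smoothing epsilon for the backbone loss.
#' @param adam an [adam_config()].
#' @param seed master seed for the run.
#' @param small logical; apply the scaled-down preset.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(gaussian_sigma = 1.0, gaussian_size = 5L,
                            lbp_side = 227L,
                            backbone = backbone_spec("smallcnn", 64L, 64L),
                            keep_n = 1186L,
                            lstm_hidden = 128L, lstm_step_width = 7L,
                            lstm_fc_units = 16L,
                            train_fraction = 0.75,
                            backbone_epochs = 10L, classifier_epochs = 40L,
                            batch_size = 16L, label_smoothing = 0.1,
                            adam = adam_config(), seed = 0L, small = FALSE) {
  if (isTRUE(small)) {
    lbp_side <- 64L
    keep_n <- 200L
    lstm_hidden <- 32L
  }
  structure(list(
    gaussian_sigma = gaussian_sigma, gaussian_size = as.integer(gaussian_size),
    lbp_side = as.integer(lbp_side), backbone = backbone,
    keep_n = as.integer(keep_n),
    lstm_hidden = as.integer(lstm_hidden),
    lstm_step_width = as.integer(lstm_step_width),
    lstm_fc_units = as.integer(lstm_fc_units),
    train_fraction = train_fraction,
    backbone_epochs = as.integer(backbone_epochs),
    classifier_epochs = as.integer(classifier_epochs),
    batch_size = as.integer(batch_size),
    label_smoothing = label_smoothing,
    adam = adam, seed = as.integer(seed)
  ), class = "pipeline_config")
}

# read one image and produce both branch inputs
preprocess_one <- function(path, config) {
  img <- read_image(path)
  if (dim(img)[3] == 1L) {
    img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))  # documented coercion
  }
  img <- gaussian_smooth(img, gaussian_kernel_spec(config$gaussian_sigma,
                                                   config$gaussian_size))
  list(
    lbp_input = to_grayscale(resize_image(img, config$lbp_side)),
    deep_input = resize_image(img, config$backbone$input_side)
  )
}

branch_features <- function(pre, backbone) {
  list(lbp = lbp_histogram(lbp_image(pre$lbp_input)),
       deep = extract_features(pre$deep_input, backbone))
}

#' Train the full pipeline
#'
#' Discovers `<root>/<class>/*.png|jpg`, splits per class (seeded,
#' stratified), trains the backbone head on the training split, fits the
#' entropy selection on training-split features only, trains the LSTM
#' classifier on the selected features, and evaluates on the held-out split.
#'
#' @param data_root dataset root with one directory per class.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for run artifacts (`config.json`,
#'   `metrics.json`, `roc.csv`, `selection.json`, `bundle.rds`).
#' @param verbose print stage progress.
#' @return list with `bundle` (a `model_bundle`), `metrics`, `roc`,
#'   `validation` (per-image predictions on the held-out split).
#' @export
run_training <- function(data_root, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  manifest <- discover_images(data_root)
  split <- split_dataset(manifest, config$train_fraction, seed = config$seed)
  if (nrow(split$train) == 0L || nrow(split$validation) == 0L) {
    stop("empty split: check train_fraction and per-class image counts",
         call. = FALSE)
  }
  say("split: %d train / %d validation images",
      nrow(split$train), nrow(split$validation))

  say("preprocessing %d images (Gaussian sigma=%.2f size=%d)",
      nrow(manifest), config$gaussian_sigma, config$gaussian_size)
  pre_train <- lapply(split$train$path, preprocess_one, config = config)
  pre_val <- lapply(split$validation$path, preprocess_one, config = config)

  backbone <- create_backbone(config$backbone, seed = config$seed + 17L)
  if (config$backbone_epochs > 0L) {
    say("training backbone head: %d epochs", config$backbone_epochs)
    backbone <- train_backbone(
      lapply(pre_train, `[[`, "deep_input"), split$train$class, backbone,
      adam = config$adam, label_smoothing = config$label_smoothing,
      epochs = config$backbone_epochs, batch_size = config$batch_size,
      seed = config$seed + 29L)
  }

  say("extracting branch features")
  feat_train <- lapply(pre_train, branch_features, backbone = backbone)
  feat_val <- lapply(pre_val, branch_features, backbone = backbone)
  deep_train <- do.call(rbind, lapply(feat_train, `[[`, "deep"))
  lbp_train <- do.call(rbind, lapply(feat_train, `[[`, "lbp"))
  deep_val <- do.call(rbind, lapply(feat_val, `[[`, "deep"))
  lbp_val <- do.call(rbind, lapply(feat_val, `[[`, "lbp"))

  say("fitting entropy selection (keep_n=%d of %d fused)",
      config$keep_n, ncol(deep_train) + ncol(lbp_train))
  selection <- fit_selection(deep_train, lbp_train, keep_n = config$keep_n)
  X_train <- apply_selection(selection, deep_train, lbp_train)
  X_val <- apply_selection(selection, deep_val, lbp_val)

  say("training LSTM classifier: %d epochs on %d x %d features",
      config$classifier_epochs, nrow(X_train), ncol(X_train))
  lcfg <- lstm_config(step_width = config$lstm_step_width,
                      hidden = config$lstm_hidden,
                      num_classes = 2L, fc_units = config$lstm_fc_units,
                      seed = config$seed + 41L)
  classifier <- train_classifier(X_train, split$train$class, lcfg,
                                 adam = config$adam,
                                 epochs = config$classifier_epochs,
                                 batch_size = config$batch_size)

  pred <- predict_classifier(classifier, X_val)
  counts <- confusion(split$validation$class, pred$labels)
  metrics <- compute_metrics(counts)
  roc <- roc_curve(split$validation$class, pred$scores)
  say("validation accuracy %.3f, AUC %.3f (%.1f s)",
      metrics$accuracy, roc$auc, as.numeric(difftime(Sys.time(), t0, "secs")))

  bundle <- structure(list(config = config, backbone = backbone,
                           selection = selection, classifier = classifier),
                      class = "model_bundle")
  validation <- data.frame(path = split$validation$path,
                           class = split$validation$class,
                           predicted = pred$labels, score = pred$scores,
                           stringsAsFactors = FALSE)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_json <- config
    cfg_json$backbone <- unclass(cfg_json$backbone)
    cfg_json$adam <- unclass(cfg_json$adam)
    jsonlite::write_json(unclass(cfg_json), file.path(out_dir, "config.json"),
                         digits = NA, auto_unbox = TRUE)
    write_metrics(metrics, roc, out_dir)
    write_selection_json(selection, file.path(out_dir, "selection.json"))
    saveRDS(bundle, file.path(out_dir, "bundle.rds"))
  }

  list(bundle = bundle, metrics = metrics, roc = roc, validation = validation)
}

#' Predict classes for new images with a trained bundle
#'
#' Applies the stored preprocessing, branch statistics, frozen selection
#' indices and classifier weights. Unreadable files produce an error entry
#' and the run continues.
#'
#' @param bundle a `model_bundle` from [run_training()] (or loaded from
#'   `bundle.rds`).
#' @param paths character vector of image paths.
#' @return data.frame `path`, `predicted`, `score`, `error` (NA on success).
#' @export
run_prediction <- function(bundle, paths) {
  stopifnot(inherits(bundle, "model_bundle"))
  if (length(paths) == 0L) {
    return(data.frame(path = character(0), predicted = character(0),
                      score = numeric(0), error = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      pre <- preprocess_one(p, bundle$config)
      ft <- branch_features(pre, bundle$backbone)
      X <- apply_selection(bundle$selection, ft$deep, ft$lbp)
      pr <- predict_classifier(bundle$classifier, X)
      data.frame(path = p, predicted = pr$labels[1], score = pr$scores[1],
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(path = p, predicted = NA_character_, score = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
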