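## The main model-fitting entry point: preprocessing -> block LBP
## histograms -> eigenface projection -> (GA-evolved or fixed) MLP, with a
## contiguous-block train/test split and CCR reporting.

#' Run configuration for a full age-estimation fit
#'
#' Collects every stage's parameters. All randomness (weight
#' initialization, GA evolution, mutation) is governed by `seed`.
#'
#' @param size Square face-crop side length S (default 100).
#' @param grid LBP block grid c(rows, cols) (default 7x7).
#' @param lbp_mode LBP threshold mode, `"strict"` (bit set iff the
#'   neighbor exceeds the centre) or `"geq"`.
#' @param k Retained eigenface components; NULL selects the smallest K
#'   reaching `var_target` cumulative variance.
#' @param var_target Cumulative variance target for automatic K.
#' @param method `"ga"` (configuration evolved by the genetic algorithm)
#'   or `"ann"` (single network with the fixed `network` configuration).
#' @param ga A [ga_config()] (used when `method = "ga"`).
#' @param network A [network_config()] (used when `method = "ann"`, and as
#'   the goal/epoch template for GA candidates).
#' @param train_frac Contiguous-block training fraction (default 0.8).
#' @param detector Optional face-detector function (see
#'   [detect_and_crop()]); NULL uses the deterministic centre-crop
#'   fallback.
#' @param seed Integer master seed.
#' @return List of class `"faceage_config"`.
#' @export
faceage_config <- function(size = 100L, grid = c(7L, 7L),
                           lbp_mode = c("strict", "geq"),
                           k = NULL, var_target = 0.95,
                           method = c("ga", "ann"),
                           ga = ga_config(), network = network_config(),
                           train_frac = 0.8, detector = NULL, seed = 1L) {
  lbp_mode <- match.arg(lbp_mode)
  method <- match.arg(method)
  stopifnot(size >= 8, length(grid) == 2, all(grid >= 1),
            var_target > 0, var_target <= 1,
            train_frac > 0, train_frac < 1,
            inherits(ga, "ga_config"), inherits(network, "network_config"))
  structure(list(size = as.integer(size), grid = as.integer(grid),
                 lbp_mode = lbp_mode, k = k, var_target = var_target,
                 method = method, ga = ga, network = network,
                 train_frac = train_frac, detector = detector,
                 seed = as.integer(seed)),
            class = "faceage_config")
}

## Deterministic stratified order: spreads each group evenly over the
## sequence so a contiguous block split contains every group in both
## blocks regardless of how the corpus was stored on disk.
stratified_block_order <- function(labels) {
  counts <- table(factor(labels, levels = sort(unique(labels))))
  pos <- stats::ave(seq_along(labels), labels, FUN = seq_along)
  key <- (pos - 0.5) / as.numeric(counts[as.character(labels)])
  order(key, labels)
}

faceage_features <- function(images, config) {
  pre <- lapply(images, preprocess_image, detector = config$detector,
                size = config$size)
  lbp_features(pre, grid = config$grid, mode = config$lbp_mode)
}

#' Fit the age-group classification model
#'
#' Runs the full pipeline: each image is grayscaled, face-cropped (centre
#' fallback), resized to S x S and histogram-equalized; block-wise LBP
#' histograms are computed and projected into an eigenface basis fit on
#' the training block; and a single hidden-layer perceptron is trained on
#' the projections — either with a fixed configuration (`method = "ann"`)
#' or with hidden width, learning rate, damping mu and mu-decrease evolved
#' by the genetic algorithm with fitness 1/MSE (`method = "ga"`). Samples
#' are reordered by a deterministic stratified interleave and split into
#' contiguous training (first `train_frac`) and test blocks; the held-out
#' block yields the reported per-group CCR table.
#'
#' @param x A corpus directory (layout of [load_corpus()]), a
#'   `"synth_corpus"`, or a list of raw image matrices.
#' @param labels Integer labels 0-7, required when `x` is a plain list.
#' @param config A [faceage_config()].
#' @return Object of class `"faceage"` with components `basis`
#'   (eigenbasis), `fit` (the trained `"mlp_fit"`), `ga` (the
#'   `"ga_result"`, or NULL for `method = "ann"`), `test_report`,
#'   `train_report`, `split`, `config`, `n`.
#' @export
faceage <- function(x, labels = NULL, config = faceage_config()) {
  stopifnot(inherits(config, "faceage_config"))
  if (is.character(x)) {
    corpus <- load_corpus(x)
    images <- corpus$images; labels <- corpus$labels
  } else if (inherits(x, "synth_corpus")) {
    images <- x$images; labels <- x$labels
  } else {
    images <- x
    if (is.null(labels)) stop("labels are required for a plain image list",
                              call. = FALSE)
  }
  stopifnot(length(images) == length(labels), all(labels %in% 0:7))
  feats <- faceage_features(images, config)
  ord <- stratified_block_order(labels)
  feats <- feats[ord, , drop = FALSE]
  labels <- labels[ord]
  split <- divide_block(length(labels), config$train_frac)

  basis <- fit_eigenspace(feats[split$train, , drop = FALSE],
                          k = config$k, var_target = config$var_target)
  w_train <- eigen_project(basis, feats[split$train, , drop = FALSE])
  targets <- one_hot(labels[split$train], 8L)

  ga_res <- NULL
  if (config$method == "ga") {
    ga_res <- ga_evolve(w_train, labels[split$train], config$ga,
                        n_out = 8L,
                        final_max_epochs = config$network$max_epochs,
                        seed = config$seed)
    fit <- ga_res$best$fit
  } else {
    set.seed(config$seed)
    net <- mlp_init(ncol(w_train), config$network$hidden_size, 8L)
    fit <- mlp_train(net, w_train, targets, config$network)
  }

  train_pred <- predict_group(fit$net, w_train)
  train_report <- per_group_report(train_pred, labels[split$train])
  test_report <- NULL
  if (length(split$test) > 0) {
    w_test <- eigen_project(basis, feats[split$test, , drop = FALSE])
    test_pred <- predict_group(fit$net, w_test)
    test_report <- per_group_report(test_pred, labels[split$test])
  }
  structure(list(basis = basis, fit = fit, ga = ga_res,
                 test_report = test_report, train_report = train_report,
                 split = split, config = config, n = length(labels),
                 train_pred = train_pred, labels = labels),
            class = "faceage")
}

#' Predict age groups for new images
#'
#' Test-time pipeline: preprocessing and LBP extraction as at training
#' time, then the training mean is subtracted and the feature projected
#' into the training eigenface space before the network is applied.
#'
#' @param object A fitted `"faceage"` model.
#' @param newdata A corpus directory, a `"synth_corpus"`, a list of image
#'   matrices, or a single image matrix.
#' @param type `"group"` (0-based indices), `"label"` (bracket names) or
#'   `"scores"` (the 8 output scores per image).
#' @param ... Unused.
#' @return Integer vector, character vector, or score matrix.
#' @export
predict.faceage <- function(object, newdata,
                            type = c("group", "label", "scores"), ...) {
  type <- match.arg(type)
  if (is.character(newdata)) {
    newdata <- load_corpus(newdata)$images
  } else if (inherits(newdata, "synth_corpus")) {
    newdata <- newdata$images
  } else if (is.matrix(newdata) || (is.array(newdata) &&
                                    length(dim(newdata)) == 3)) {
    newdata <- list(newdata)
  }
  feats <- faceage_features(newdata, object$config)
  if (ncol(feats) != object$basis$d) {
    stop("feature dimension does not match the model archive ",
         "(different crop size or LBP grid)", call. = FALSE)
  }
  w <- eigen_project(object$basis, feats)
  scores <- mlp_forward(object$fit$net, w)
  switch(type,
         scores = scores,
         group = max.col(scores, ties.method = "first") - 1L,
         label = age_group_labels()[max.col(scores, ties.method = "first")])
}

#' Evaluate a fitted model on a labeled corpus
#'
#' @param object A `"faceage"` model.
#' @param x Corpus directory, `"synth_corpus"`, or list of images.
#' @param labels Labels when `x` is a plain list.
#' @return An `"evaluation_report"`.
#' @export
evaluate_model <- function(object, x, labels = NULL) {
  stopifnot(inherits(object, "faceage"))
  if (is.character(x)) {
    corpus <- load_corpus(x); images <- corpus$images; labels <- corpus$labels
  } else if (inherits(x, "synth_corpus")) {
    images <- x$images; labels <- x$labels
  } else {
    images <- x
    if (is.null(labels)) stop("labels required", call. = FALSE)
  }
  pred <- predict(object, images)
  per_group_report(pred, labels)
}

#' @export
print.faceage <- function(x, ...) {
  cat("Age-group classifier (LBP + eigenfaces + ",
      if (x$config$method == "ga") "GA-evolved MLP" else "MLP",
      ")\n", sep = "")
  cat(sprintf("  %d images; %d train / %d test (contiguous blocks)\n",
              x$n, length(x$split$train), length(x$split$test)))
  cat(sprintf("  crop %dx%d, LBP grid %dx%d (%s), %d eigen components\n",
              x$config$size, x$config$size, x$config$grid[1],
              x$config$grid[2], x$config$lbp_mode, x$basis$k))
  cat(sprintf("  network %d-%d-%d, training MSE %.4g\n",
              x$fit$net$n_in, x$fit$net$n_hidden, x$fit$net$n_out, x$fit$mse))
  if (!is.null(x$test_report)) {
    cat(sprintf("  held-out CCR: %.2f%% (%d/%d)\n", x$test_report$total$ccr,
                x$test_report$total$correct, x$test_report$total$n))
  }
  invisible(x)
}

#' @export
summary.faceage <- function(object, ...) {
  print(object)
  if (!is.null(object$ga)) {
    cat("\nGA evolution log:\n")
    print(object$ga$log, row.names = FALSE)
  }
  if (!is.null(object$test_report)) {
    cat("\nHeld-out per-group report:\n")
    print(object$test_report)
  }
  invisible(object)
}

#' @export
coef.faceage <- function(object, ...) {
  if (!is.null(object$ga)) object$ga$best$chromosome else
    unlist(object$config$network[c("hidden_size", "learning_rate",
                                   "mu", "mu_dec")])
}

#' @export
fitted.faceage <- function(object, ...) {
  object$train_pred
}

#' @export
plot.faceage <- function(x, ...) {
  if (!is.null(x$ga)) {
    log <- x$ga$log
    graphics::plot(log$generation, log$best_fitness, type = "b", pch = 19,
                   xlab = "generation", ylab = "fitness (1/MSE)",
                   main = "GA evolution", ...)
    graphics::lines(log$generation, log$mean_fitness, type = "b", lty = 2)
    graphics::legend("topleft", legend = c("best", "mean"),
                     lty = c(1, 2), pch = c(19, 1), bty = "n")
  } else {
    tr <- x$fit$trace
    graphics::plot(tr$epoch, tr$mse, type = "l", log = "y",
                   xlab = "epoch", ylab = "training MSE",
                   main = "Training trace", ...)
  }
  invisible(x)
}

#' Save / load a fitted model archive
#'
#' The archive bundles the run configuration, the eigenface basis, the
#' trained network and the GA log.
#'
#' @param object A `"faceage"` model.
#' @param path Archive path (.rds).
#' @return `path` (save) or the restored model (load).
#' @export
save_faceage <- function(object, path) {
  stopifnot(inherits(object, "faceage"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_faceage
#' @export
load_faceage <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "faceage")) stop("not a faceage model archive",
                                      call. = FALSE)
  obj
}
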