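#' Training configuration
#'
#' The reference recipe trains for 200 epochs with Adam, cross-entropy loss,
#' an initial learning rate of 0.001 decayed by a factor of 10 every 50
#' epochs, and grayscale inputs resized to 224 x 288 with per-image
#' standardization. Batch size defaults to 32. All fields are configurable;
#' scaled-down runs shrink `epochs`, `decay_every` and `input_size` together.
#'
#' @param epochs Number of training epochs (>= 1).
#' @param initial_lr Initial learning rate (> 0).
#' @param decay_factor Multiplicative decay divisor (>= 1).
#' @param decay_every Epochs between decays (>= 1).
#' @param batch_size Mini-batch size.
#' @param input_size `(height, width)` the loader resizes images to.
#' @param seed Integer seed controlling initialization and batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, initial_lr = 0.001, decay_factor = 10,
                         decay_every = 50L, batch_size = 32L,
                         input_size = c(224L, 288L), seed = 1L) {
  stopifnot(epochs >= 1, initial_lr > 0, decay_factor >= 1, decay_every >= 1,
            batch_size >= 1, length(input_size) == 2L)
  structure(
    list(epochs = as.integer(epochs), initial_lr = initial_lr,
         decay_factor = decay_factor, decay_every = as.integer(decay_every),
         batch_size = as.integer(batch_size),
         input_size = as.integer(input_size), seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate at a given epoch
#'
#' The schedule is piecewise constant:
#' `initial_lr / decay_factor^((epoch - 1) %/% decay_every)` for 1-based
#' epochs, i.e. 0.001 for epochs 1-50, 1e-4 for 51-100, 1e-5 for 101-150 and
#' 1e-6 for 151-200 under the reference configuration.
#'
#' @param epoch 1-based epoch index in `1..epochs`.
#' @param config A [train_config()].
#' @return The learning rate, a single number.
#' @examples
#' lr_at(1, train_config())    # 0.001
#' lr_at(51, train_config())   # 1e-4
#' @export
lr_at <- function(epoch, config) {
  stopifnot(inherits(config, "train_config"))
  if (any(epoch < 1 | epoch > config$epochs)) {
    stop(sprintf("epoch must lie in 1..%d", config$epochs), call. = FALSE)
  }
  config$initial_lr / config$decay_factor^((epoch - 1) %/% config$decay_every)
}

# Load the images of a manifest subset into an (H, W, N) array, resizing
# when the stored size differs from input_size.
load_images <- function(manifest, input_size) {
  n <- nrow(manifest)
  H <- input_size[1]; W <- input_size[2]
  x <- array(0, dim = c(H, W, n))
  for (i in seq_len(n)) {
    img <- read_gray_png(manifest$path[i])
    if (!all(dim(img) == c(H, W))) {
      img <- EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                                w = H, h = W))
      img <- matrix(img, H, W)
    }
    x[, , i] <- img
  }
  x
}

category_levels <- function(manifest) sort(unique(manifest$category))

#' Train a network on a manifest
#'
#' Runs the seeded training loop: Adam updates on softmax cross-entropy with
#' the stepped learning-rate schedule of [lr_at()], mini-batches reshuffled
#' every epoch, batch statistics for normalization during training and
#' running averages at evaluation. Per-image standardization is applied
#' after loading. The retained checkpoint is the epoch with the best
#' validation accuracy (earliest epoch on ties); the fitted model carries
#' those weights.
#'
#' @param spec An `archspec`.
#' @param manifest A manifest whose `split` column marks `train` and `val`
#'   records (augmented records train alongside originals).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return An object of class `sononet_fit`: list with `model` (the selected
#'   checkpoint as a `sononet_model`), `history` (data frame: epoch, lr,
#'   train_loss, train_acc, val_loss, val_acc), `best_epoch`, `categories`
#'   (label order used for class indices), and `config`.
#' @export
train_network <- function(spec, manifest, config = train_config(),
                          verbose = FALSE) {
  validate_archspec(spec)
  stopifnot(inherits(config, "train_config"))
  check_manifest(manifest)
  tr <- manifest[manifest$split %in% "train", , drop = FALSE]
  va <- manifest[manifest$split %in% "val", , drop = FALSE]
  if (nrow(tr) == 0L) stop("training split is empty", call. = FALSE)
  if (nrow(va) == 0L) stop("validation split is empty", call. = FALSE)
  cats <- category_levels(tr)
  K <- spec$num_classes
  if (length(cats) != K) {
    stop(sprintf("manifest has %d categories but the architecture expects %d classes",
                 length(cats), K), call. = FALSE)
  }
  x_tr <- standardize_batch(load_images(tr, config$input_size))
  y_tr <- match(tr$category, cats) - 1L
  x_va <- standardize_batch(load_images(va, config$input_size))
  y_va <- match(va$category, cats) - 1L

  model <- sononet_model(spec, seed = config$seed)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n_tr <- length(y_tr)
  bs <- config$batch_size
  hist <- data.frame()
  best_acc <- -Inf; best_epoch <- NA_integer_; best_params <- NULL
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(epoch, config)
    perm <- sample.int(n_tr)
    loss_sum <- 0; correct <- 0L
    for (start in seq(1L, n_tr, by = bs)) {
      take <- perm[start:min(start + bs - 1L, n_tr)]
      res <- .net_train_batch(model$ptr, x_tr[, , take, drop = FALSE],
                              y_tr[take], lr)
      loss_sum <- loss_sum + res$loss * length(take)
      correct <- correct + sum(max.col(res$logits, ties.method = "first") - 1L ==
                                 y_tr[take])
    }
    ev <- eval_split(model, x_va, y_va, bs)
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = loss_sum / n_tr,
                      train_acc = correct / n_tr,
                      val_loss = ev$loss, val_acc = ev$acc)
    hist <- rbind(hist, row)
    if (ev$acc > best_acc) {
      best_acc <- ev$acc; best_epoch <- epoch
      best_params <- model_parameters(model)
    }
    if (verbose) {
      message(sprintf("epoch %3d lr %.1e | train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, lr, row$train_loss, row$train_acc, row$val_loss,
                      row$val_acc))
    }
  }
  set_model_parameters(model, best_params)
  .net_release(model$ptr)
  structure(
    list(model = model, history = hist, best_epoch = best_epoch,
         categories = cats, config = config),
    class = "sononet_fit"
  )
}

eval_split <- function(model, x, y, batch_size) {
  n <- length(y)
  loss_sum <- 0; correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    res <- .net_eval_loss(model$ptr, x[, , take, drop = FALSE], y[take])
    loss_sum <- loss_sum + res$loss * length(take)
    correct <- correct + sum(max.col(res$logits, ties.method = "first") - 1L ==
                               y[take])
  }
  list(loss = loss_sum / n, acc = correct / n)
}

#' @export
print.sononet_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<sononet fit> %s, %d epochs; best val acc %.3f at epoch %d (final %.3f)\n",
              x$model$spec$name, nrow(x$history),
              max(x$history$val_acc), x$best_epoch, last$val_acc))
  invisible(x)
}

#' Evaluate a fitted model on a manifest split
#'
#' Predicts every record of the requested split, builds the confusion matrix
#' (rows true, columns predicted, argmax with lowest-index tie-break) and
#' derives accuracy, macro sensitivity, and macro specificity.
#'
#' @param fit A `sononet_fit` (or a `sononet_model` plus `categories`).
#' @param manifest The manifest to evaluate on.
#' @param split Which split to use (`"test"` by default).
#' @param categories Category-to-class mapping; defaults to the fit's.
#' @return List with `confusion` (the matrix), `metrics`
#'   ([classification_metrics()] report), `predicted` and `true` class
#'   indices.
#' @export
evaluate_network <- function(fit, manifest, split = "test",
                             categories = NULL) {
  if (inherits(fit, "sononet_fit")) {
    model <- fit$model
    if (is.null(categories)) categories <- fit$categories
    config <- fit$config
  } else {
    model <- fit
    if (is.null(categories)) stop("categories must be given for a bare model",
                                  call. = FALSE)
    config <- train_config(epochs = 1L)
  }
  check_manifest(manifest)
  sub <- manifest[manifest$split %in% split, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("split '%s' is empty", split), call. = FALSE)
  x <- standardize_batch(load_images(sub, config$input_size))
  y <- match(sub$category, categories)
  if (anyNA(y)) stop("manifest contains categories unseen in training", call. = FALSE)
  K <- model$spec$num_classes
  pred <- integer(nrow(sub))
  for (start in seq(1L, nrow(sub), by = config$batch_size)) {
    take <- start:min(start + config$batch_size - 1L, nrow(sub))
    logits <- forward(model, x[, , take, drop = FALSE], train = FALSE)
    pred[take] <- max.col(logits, ties.method = "first")
  }
  cm <- confusion(y, pred, K)
  list(confusion = cm, metrics = classification_metrics(cm),
       predicted = pred, true = y)
}
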